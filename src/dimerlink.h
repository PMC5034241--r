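#ifndef DIMERLINK_H
#define DIMERLINK_H

#include <cstddef>

// Midpoint-rule Gauss double sum over two segment sets given as flat arrays
// (row-major x,y,z per segment). Returns the dimensionless sum; writes the
// minimal midpoint-midpoint distance and the argmin pair (0-based) so callers
// can detect singular pairs.
double gauss_midpoint_sum(const double* m1, const double* b1, std::size_t n1,
                          const double* m2, const double* b2, std::size_t n2,
                          double* min_dist, std::size_t* argmin_i,
                          std::size_t* argmin_j);

// Gaussian entanglement of two open chains given vertex coordinates
// (row-major x,y,z per vertex). Segments are built internally.
double gauss_open_chains(const double* xa, std::size_t na,
                         const double* xb, std::size_t nb);

#endif
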