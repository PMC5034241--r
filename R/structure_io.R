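#' Calpha chain constructor
#'
#' An ordered Calpha trace of one protein chain, N-terminal to C-terminal.
#' All downstream entanglement measures use the sign convention fixed by this
#' N-to-C orientation.
#'
#' @param coords numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom), ordered N-terminus to C-terminus.
#' @param chain_id short chain label, e.g. "A".
#' @return An object of class `ca_chain` with elements `chain_id`, `coords`
#'   and `n_residues`.
#' @export
ca_chain <- function(coords, chain_id = "A") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have three columns (x, y, z)")
  if (nrow(coords) < 3L)
    stop("chain too short: need at least 3 Calpha atoms, got ", nrow(coords))
  if (!all(is.finite(coords)))
    stop("coords contain non-finite values")
  d <- bond_lengths(coords)
  if (any(d <= 0))
    stop("duplicated consecutive Calpha positions")
  structure(list(chain_id = as.character(chain_id),
                 coords = unname(coords),
                 n_residues = nrow(coords)),
            class = "ca_chain")
}

bond_lengths <- function(coords) {
  sqrt(rowSums((coords[-1L, , drop = FALSE] -
                  coords[-nrow(coords), , drop = FALSE])^2))
}

#' @export
print.ca_chain <- function(x, ...) {
  cat("<ca_chain> chain", x$chain_id, "with", x$n_residues, "residues\n")
  invisible(x)
}

#' Pair two Calpha chains into a dimer
#'
#' Applies the backbone-integrity gap filter to both chains; a dimer failing
#' it is kept but flagged `rejected`, since a hole in the trace makes any
#' linking estimate unreliable.
#'
#' @param chain_a,chain_b [ca_chain] objects.
#' @param pdb_id identifier string.
#' @param gap_threshold maximal allowed consecutive Calpha-Calpha distance in
#'   Angstrom (default 10).
#' @return An object of class `dimer_structure`: `pdb_id`, `chain_a`,
#'   `chain_b`, logical `rejected`, and `gap_violations` (per-chain bond
#'   indices exceeding the threshold).
#' @export
dimer_structure <- function(chain_a, chain_b, pdb_id = "SYNTH",
                            gap_threshold = 10) {
  stopifnot(inherits(chain_a, "ca_chain"), inherits(chain_b, "ca_chain"))
  ga <- check_gap_filter(chain_a, gap_threshold)
  gb <- check_gap_filter(chain_b, gap_threshold)
  structure(list(pdb_id = as.character(pdb_id),
                 chain_a = chain_a, chain_b = chain_b,
                 rejected = !(ga$pass && gb$pass),
                 gap_violations = list(a = ga$violations, b = gb$violations)),
            class = "dimer_structure")
}

#' @export
print.dimer_structure <- function(x, ...) {
  cat("<dimer_structure>", x$pdb_id, "- chains",
      x$chain_a$chain_id, sprintf("(%d res)", x$chain_a$n_residues), "/",
      x$chain_b$chain_id, sprintf("(%d res)", x$chain_b$n_residues),
      if (x$rejected) "[REJECTED: gap filter]" else "", "\n")
  invisible(x)
}

#' Read the two Calpha traces of a dimer from a PDB file
#'
#' Parses ATOM records (via \pkg{bio3d}), keeps only CA atoms of polymer
#' chains, resolves alternate locations to the highest occupancy (first
#' record on ties), orders residues by residue sequence number (insertion
#' codes stay in file order) and returns the two selected chains as a
#' [dimer_structure]. HETATM records and waters are ignored.
#'
#' @param path PDB file path.
#' @param chain_ids optional character vector of two chain labels. When
#'   omitted, the two chains with the most Calpha atoms are used (ties broken
#'   by file order).
#' @param gap_threshold passed to [dimer_structure()].
#' @return A [dimer_structure].
#' @export
read_ca_chains <- function(path, chain_ids = NULL, gap_threshold = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA" & !(at$resid %in% "HOH"), ,
           drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha ATOM records in ", path)
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  ca$insert[is.na(ca$insert)] <- ""
  ca$file_order <- seq_len(nrow(ca))

  # resolve altlocs: per (chain, resno, insert) keep highest occupancy,
  # first record on ties
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(ca)), key), function(idx) {
    idx[which.max(ca$o[idx])]
  }), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]

  counts <- table(ca$chain)[unique(ca$chain)] # file order
  if (is.null(chain_ids)) {
    if (length(counts) < 2L)
      stop("not a dimer: found ", length(counts), " polymer chain(s) in ",
           path)
    chain_ids <- names(sort(counts, decreasing = TRUE))[1:2]
    # keep the two largest, in file order
    chain_ids <- names(counts)[names(counts) %in% chain_ids][1:2]
  } else {
    chain_ids <- as.character(chain_ids)
    if (length(chain_ids) != 2L) stop("chain_ids must name exactly 2 chains")
    missing <- setdiff(chain_ids, names(counts))
    if (length(missing))
      stop("chain(s) not present in file: ", paste(missing, collapse = ", "))
  }

  extract <- function(id) {
    sub <- ca[ca$chain == id, , drop = FALSE]
    # order by residue number; insertion codes within a resno keep file order
    sub <- sub[order(sub$resno, sub$file_order), , drop = FALSE]
    if (nrow(sub) < 3L)
      stop("chain too short: chain ", id, " has ", nrow(sub), " Calpha atoms")
    ca_chain(as.matrix(sub[, c("x", "y", "z")]), chain_id = id)
  }

  pdb_id <- toupper(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path),
                        ignore.case = TRUE))
  dimer_structure(extract(chain_ids[1L]), extract(chain_ids[2L]),
                  pdb_id = pdb_id, gap_threshold = gap_threshold)
}

#' Backbone-integrity gap filter
#'
#' A chain is rejected when any two consecutively listed Calpha atoms are
#' more than `threshold` Angstrom apart: such a hole cannot be bridged
#' without inventing geometry, and would corrupt the linking estimate. The
#' inequality is strict, so a bond of exactly `threshold` passes.
#'
#' @param chain a [ca_chain].
#' @param threshold maximal allowed consecutive distance in Angstrom.
#' @return A list with `pass` (logical) and `violations` (1-based bond
#'   indices; bond i joins residues i and i+1).
#' @export
check_gap_filter <- function(chain, threshold = 10) {
  stopifnot(inherits(chain, "ca_chain"))
  d <- bond_lengths(chain$coords)
  bad <- which(d > threshold)
  list(pass = length(bad) == 0L, violations = as.integer(bad))
}
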