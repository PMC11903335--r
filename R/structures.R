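#' Single polypeptide chain (C-alpha trace)
#'
#' The package models a chain as its ordered C-alpha coordinates plus the
#' residue labels needed for reporting. Residue indexing inside the library
#' is positional (1-based file order); author residue numbers are carried
#' along but never used for alignment.
#'
#' @param chain_id Chain identifier (author chain id).
#' @param ca_coords n x 3 matrix of C-alpha coordinates, Angstrom.
#' @param residue_names Character vector of 3-letter residue codes.
#' @param residue_numbers Author residue identifiers (number plus optional
#'   insertion code), as a character vector.
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, ca_coords,
                            residue_names = NULL, residue_numbers = NULL) {
  ca_coords <- as_coord_matrix(ca_coords)
  n <- nrow(ca_coords)
  if (n < 1L) stop("a chain needs at least one residue")
  if (is.null(residue_names)) residue_names <- rep("ALA", n)
  if (is.null(residue_numbers)) residue_numbers <- as.character(seq_len(n))
  residue_numbers <- as.character(residue_numbers)
  if (length(residue_names) != n || length(residue_numbers) != n)
    stop("residue annotations must match the number of C-alpha atoms")
  if (anyDuplicated(residue_numbers))
    stop("duplicate residue identifiers within chain ", chain_id)
  structure(list(chain_id = as.character(chain_id), ca_coords = ca_coords,
                 residue_names = as.character(residue_names),
                 residue_numbers = residue_numbers),
            class = "chain_structure")
}

chain_length <- function(chain) nrow(chain$ca_coords)

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> chain %s, %d residues\n",
              x$chain_id, chain_length(x)))
  invisible(x)
}

#' Protein complex (set of chains)
#'
#' @param complex_id Identifier for the complex (typically the file stem).
#' @param chains List of [chain_structure()] objects with unique chain ids.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(complex_id, chains) {
  if (length(chains) < 1L) stop("a complex needs at least one chain")
  ids <- vapply(chains, function(c) c$chain_id, character(1))
  if (anyDuplicated(ids)) stop("chain ids must be unique within a complex")
  structure(list(complex_id = as.character(complex_id), chains = chains),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  lens <- vapply(x$chains, chain_length, integer(1))
  cat(sprintf("<complex_structure> %s: %d chain(s) [%s], %d residues\n",
              x$complex_id, length(x$chains),
              paste(chain_ids(x), collapse = ","), sum(lens)))
  invisible(x)
}

#' Total residue count of a complex
#' @param x A [complex_structure()].
#' @return Integer: the sum of chain lengths (the L used to normalize
#'   complex TM-scores).
#' @export
total_length <- function(x) {
  sum(vapply(x$chains, chain_length, integer(1)))
}

#' Chain identifiers of a complex
#' @param x A [complex_structure()].
#' @return Character vector of chain ids in file order.
#' @export
chain_ids <- function(x) vapply(x$chains, function(c) c$chain_id, character(1))

#' Read a structure file into a complex
#'
#' Reads a PDB or mmCIF file into a [complex_structure()]. Only the first
#' model of multi-model files is used; only C-alpha atoms with alternate
#' location '' or 'A' are kept; HETATM-only chains (ligands, waters) are
#' dropped; chains with fewer than 3 C-alpha atoms are dropped with a
#' warning (a rigid superposition needs at least 3 points). For mmCIF the
#' author chain identifiers (auth_asym_id) are used.
#'
#' Parsing is delegated to \pkg{bio3d}.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format Either `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @return A [complex_structure()]; its `complex_id` is the file stem.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif")
      suppressMessages(suppressWarnings(
        bio3d::read.cif(path, multi = FALSE, verbose = FALSE)))
    else
      suppressMessages(suppressWarnings(
        bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  atoms <- pdb$atom
  keep <- atoms$type == "ATOM" & atoms$elety == "CA" &
    (is.na(atoms$alt) | atoms$alt == "" | atoms$alt == "A")
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("no protein C-alpha atoms in ", path)
  atoms$chain[is.na(atoms$chain)] <- " "
  ins <- if ("insert" %in% names(atoms)) atoms$insert else NA
  ins[is.na(ins)] <- ""
  resnum <- paste0(atoms$resno, ins)
  chains <- list()
  for (cid in unique(atoms$chain)) {
    sel <- atoms$chain == cid
    # keep first occurrence of each residue (guards odd altloc layouts)
    first <- !duplicated(resnum[sel])
    rows <- atoms[sel, , drop = FALSE][first, , drop = FALSE]
    if (nrow(rows) < 3L) {
      warning("dropping chain ", cid, " of ", basename(path),
              ": fewer than 3 C-alpha atoms", call. = FALSE)
      next
    }
    chains[[length(chains) + 1L]] <- chain_structure(
      chain_id = cid,
      ca_coords = cbind(rows$x, rows$y, rows$z),
      residue_names = rows$resid,
      residue_numbers = resnum[sel][first])
  }
  if (length(chains) == 0L)
    stop("no usable protein chains in ", path)
  complex_structure(sub("\\.(pdb|cif|mmcif)$", "", basename(path),
                        ignore.case = TRUE), chains)
}

#' Write a complex to a minimal PDB file
#'
#' A debugging/fixture writer: one ATOM record per C-alpha, chains in
#' order, TER between chains. Coordinates are written at PDB precision
#' (3 decimals).
#'
#' @param x A [complex_structure()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (chain in x$chains) {
    n <- chain_length(chain)
    num <- suppressWarnings(as.integer(sub("[A-Za-z]$", "", chain$residue_numbers)))
    num[is.na(num)] <- seq_len(n)[is.na(num)]
    ic <- ifelse(grepl("[A-Za-z]$", chain$residue_numbers),
                 substring(chain$residue_numbers,
                           nchar(chain$residue_numbers)), " ")
    for (i in seq_len(n)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000L, chain$residue_names[i], chain$chain_id,
        num[i] %% 10000L, ic[i],
        chain$ca_coords[i, 1], chain$ca_coords[i, 2], chain$ca_coords[i, 3]),
        con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read all structures in a directory
#'
#' @param dir Directory containing `.pdb`/`.cif`/`.mmcif` files.
#' @return Named list of [complex_structure()]s (names are complex ids).
#' @export
read_structure_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(pdb|cif|mmcif)$", full.names = TRUE,
                      ignore.case = TRUE)
  out <- lapply(sort(files), read_structure)
  setNames(out, vapply(out, function(s) s$complex_id, character(1)))
}
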