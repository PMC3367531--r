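# Plain-text interchange: FASTA for secondary-structure strings, pathways
# and islands; TSV for path manifests and rate tables.

write_fasta <- function(seqs, path, names = NULL) {
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(c(paste0(">", names[k]), seqs[k]), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  setNames(toupper(unlist(recs, use.names = FALSE)),
           vapply(recs, function(r) attr(r, "name"), character(1)))
}

#' Read and write secondary-structure strings
#'
#' Accepts either a single-record plain-text file (the bare string, one
#' line) or FASTA with a description line.
#'
#' @param path File path.
#' @param ss String to write.
#' @param name FASTA record name.
#' @param fasta Write FASTA (`TRUE`) or bare text.
#' @return `read_ss` returns the (validated-alphabet) string.
#' @export
read_ss <- function(path) {
  first <- readLines(path, n = 1L)
  ss <- if (startsWith(first, ">")) unname(read_fasta(path)[1]) else
    trimws(paste(readLines(path), collapse = ""))
  ss_chars(ss)  # alphabet check
  ss
}

#' @rdname read_ss
#' @export
write_ss <- function(ss, path, name = "ss", fasta = TRUE) {
  if (fasta) write_fasta(ss, path, name) else writeLines(ss, path)
  invisible(path)
}

#' Write a pathway as multi-record FASTA and a TSV manifest
#'
#' One FASTA record per step; the manifest lists step index, move descriptor
#' and remaining distance to the destination.
#'
#' @param path_obj An `ss_path` from [ss_build_path()].
#' @param fasta_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_path <- function(path_obj, fasta_path = NULL, tsv_path = NULL) {
  steps <- path_obj$steps
  if (!is.null(fasta_path)) {
    write_fasta(steps, fasta_path,
                names = sprintf("step_%03d", seq_along(steps) - 1L))
  }
  if (!is.null(tsv_path)) {
    man <- data.frame(step = seq_along(steps) - 1L,
                      move = c("start", path_obj$moves),
                      distance_to_target = path_obj$distance,
                      ss = steps)
    write.table(man, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path_obj)
}

#' Write an island as FASTA plus a TSV energy table
#'
#' FASTA headers carry the structure id, target energy and sampling
#' temperature.
#'
#' @param island An `island` from [run_design()].
#' @param fasta_path,tsv_path Output paths (either may be `NULL`).
#' @export
write_island <- function(island, fasta_path = NULL, tsv_path = NULL) {
  nm <- sprintf("%s|%d|E=%.4f|T=%g", island$structure_id,
                seq_along(island$sequences), island$energies,
                island$temperature)
  if (!is.null(fasta_path)) write_fasta(island$sequences, fasta_path, nm)
  if (!is.null(tsv_path)) {
    write.table(
      data.frame(seq = island$sequences, energy = island$energies,
                 log_n_perm = island$log_n_perm),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(island)
}

#' Write or read a rate table as TSV
#'
#' Columns: `A`, `B`, `k_AB`, `k_BA`, `se_AB`, `se_BA`, `dE_HB`, `dN_c`,
#' `Q`, `q`, `n_eff`.
#'
#' @param rates Data frame in the rate-table layout.
#' @param path File path.
#' @return `read_rate_table` returns the data frame.
#' @export
write_rate_table <- function(rates, path) {
  write.table(rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read C-alpha coordinates of one chain from a PDB file
#'
#' Standard PDB input via bio3d; returns the C-alpha coordinate matrix in
#' residue order (1-based author numbering converted to 0-based positions by
#' ordering).
#'
#' @param path PDB file.
#' @param chain Chain identifier (default: first chain present).
#' @return Numeric n x 3 coordinate matrix (Angstrom).
#' @export
read_calpha_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA", chain = chain)
  m <- matrix(pdb$xyz[sel$xyz], ncol = 3, byrow = TRUE)
  if (nrow(m) < 4L) stop("fewer than 4 C-alpha atoms selected", call. = FALSE)
  m
}
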