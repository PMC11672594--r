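#' Read assembly-line protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet plus `X`. `order_index` records the 1-based position of each
#' protein in the file, which is taken as its position in the assembly line.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return `data.frame(id, order_index, sequence)` — one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- names(set)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs[i])
    if (bad > 0) {
      stop("invalid residue '", substr(seqs[i], bad, bad), "' in record '",
           ids[i], "' at position ", bad)
    }
    if (!nzchar(seqs[i])) stop("empty sequence in record '", ids[i], "'")
  }
  data.frame(id = ids, order_index = seq_along(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#' @param proteins data.frame with `id` and `sequence` columns.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
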