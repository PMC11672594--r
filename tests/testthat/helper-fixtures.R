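# Shared fixture builders. All sequence content is generated in code.

# a minimal single-module protein: KS(C)-AT(class)-T, optionally more
minimal_truth <- function(at = "malonyl", kr = "absent", dh = "absent",
                          er = FALSE) {
  modules <- list(
    pksdecode:::.module_entry("LM", 1, ks = "Q", at = "methylmalonyl"),
    pksdecode:::.module_entry("1", 1, at = at, kr = kr, dh = dh, er = er,
                              te = TRUE))
  truth_table(modules, protein_ids = "synMini")
}

# FASTA writer for ad-hoc records
write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(records)) {
    writeLines(c(paste0(">", nm), records[[nm]]), con)
  }
  close(con)
  path
}

# classify every scanned module of a bundle and join with the truth table
recovered_calls <- function(bundle) {
  hits <- scan_assembly_line(bundle$proteins)
  groupings <- segment_modules(hits)
  calls <- classify_hits(hits)
  key <- paste(calls$protein_id, calls$start, sep = "@")
  rows <- lapply(seq_along(groupings), function(i) {
    g <- groupings[[i]]
    out <- list(ks = NA, at = NA, kr = "absent", dh = "absent", er = FALSE)
    for (j in seq_len(nrow(g$hits))) {
      h <- g$hits[j, ]
      cl <- calls[key == paste(h$protein_id, h$start, sep = "@"), ]
      switch(h$kind,
             KS = out$ks <- cl$call,
             AT = out$at <- cl$call,
             KR = out$kr <- cl$call,
             DH = out$dh <- cl$call,
             ER = out$er <- TRUE,
             NULL)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
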