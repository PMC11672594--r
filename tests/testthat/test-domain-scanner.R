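test_that("read_fasta parses, normalizes and validates records", {
  path <- write_tmp_fasta(list(protA = "MKLAVST", protB = "acdefgh"))
  recs <- read_fasta(path)
  expect_equal(recs$id, c("protA", "protB"))
  expect_equal(recs$order_index, 1:2)
  expect_equal(recs$sequence[2], "ACDEFGH")  # lowercase uppercased

  bad <- write_tmp_fasta(list(ok = "MKL", broken = "MK1L"))
  expect_error(read_fasta(bad), "broken")
  expect_error(read_fasta(bad), "position 3")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty))
})

test_that("degenerate patterns compile and match as specified", {
  expect_equal(compile_pattern("GHSI(V)GE"), "^GHS[IV]GE$")
  expect_equal(compile_pattern("HxxxxxxxxP"), "^H.{8}P$")
  expect_true(matches_pattern("GHSVGE", "GHSI(V)GE"))
  expect_false(matches_pattern("GHSAGE", "GHSI(V)GE"))
  expect_equal(pattern_width("GHSI(V)GE"), 6L)
  expect_error(compile_pattern("GH?E"), "invalid character")
})

test_that("scan_domains recovers embedded domains with exact windows", {
  bundle <- generate_assembly(minimal_truth(at = "malonyl"), seed = 7)
  hits <- scan_domains(list(id = bundle$proteins$id[1],
                            sequence = bundle$proteins$sequence[1]))
  expect_equal(hits$kind, c("KS", "AT", "T", "KS", "AT", "T", "TE"))
  # windows equal the embedded strings recorded by the generator
  at_hits <- hits[hits$kind == "AT", ]
  feats <- bundle$features
  for (w in c("motif_I", "motif_II", "motif_III")) {
    emb <- feats$content[feats$kind == "AT" & feats$element == w]
    expect_equal(at_hits[[w]], emb)
  }
  # coordinates are 1-based inclusive: re-slicing reproduces matched text
  s <- bundle$proteins$sequence[1]
  for (i in seq_len(nrow(hits))) {
    frag <- substr(s, hits$start[i], hits$end[i])
    expect_equal(nchar(frag), hits$end[i] - hits$start[i] + 1L)
    for (w in pksdecode:::.window_columns) {
      if (!is.na(hits[[w]][i])) expect_true(grepl(hits[[w]][i], frag, fixed = TRUE))
    }
  }
})

test_that("a random protein with no anchors yields an empty hit list", {
  withr::with_seed(11, {
    s <- paste(sample(strsplit("ADEFIKLMNRTV", "")[[1]], 50, replace = TRUE),
               collapse = "")
  })
  expect_warning(
    hits <- scan_domains(list(id = "decoy", sequence = s)),
    "no KS/AT anchors")
  expect_equal(nrow(hits), 0L)
})

test_that("adding an anchor-free decoy protein never changes other hits", {
  bundle <- iru_bundle(seed = 5)
  base <- scan_assembly_line(bundle$proteins)
  withr::with_seed(12, {
    decoy <- paste(sample(strsplit("ADEFIKLMNRTV", "")[[1]], 300,
                          replace = TRUE), collapse = "")
  })
  aug <- rbind(bundle$proteins,
               data.frame(id = "decoy", order_index = 7L, sequence = decoy))
  with_decoy <- scan_assembly_line(aug)
  expect_equal(with_decoy[with_decoy$protein_id != "decoy", ], base)
})

test_that("segment_modules recovers the iru module census", {
  bundle <- iru_bundle(seed = 42)
  hits <- scan_assembly_line(bundle$proteins)
  groupings <- segment_modules(hits)
  expect_length(groupings, 13L)           # loading + 12 extension modules
  expect_true(groupings[[13]]$te_present)
  expect_false(any(vapply(groupings, function(g) isTRUE(g$ambiguous),
                          logical(1))))
  # final protein carries M11-M12 + TE: kinds in order, KS12 after T11
  last_prot <- bundle$proteins$id[6]
  kinds6 <- hits$kind[hits$protein_id == last_prot]
  expect_equal(kinds6, c("KS", "AT", "DH", "KR", "T",
                         "KS", "AT", "DH", "T", "TE"))
})

test_that("a single minimal KS-AT-T protein yields one grouping", {
  geo <- pksdecode:::pks_domain_geometry()
  withr::with_seed(3, {
    ks <- pksdecode:::.build_domain("KS", list(
      active_site_context = "DTACSSL", active_site = "C"))$chars
    at <- pksdecode:::.build_domain("AT", lapply(
      pksdecode:::.at_window_patterns("malonyl"), instantiate_motif))$chars
    tt <- pksdecode:::.build_domain("T", list())$chars
  })
  s <- paste(c(ks, at, tt), collapse = "")
  hits <- scan_domains(list(id = "mini", sequence = s))
  hits$order_index <- 1L
  groupings <- segment_modules(hits)
  expect_length(groupings, 1L)
  expect_equal(groupings[[1]]$hits$kind, c("KS", "AT", "T"))
})

test_that("shuffled hit order raises an ambiguity diagnostic", {
  bundle <- generate_assembly(minimal_truth(), seed = 9)
  hits <- scan_assembly_line(bundle$proteins)
  shuffled <- hits[c(2, 1, seq_len(nrow(hits))[-(1:2)]), ]
  groupings <- segment_modules(shuffled)
  expect_gt(length(attr(groupings, "diagnostics")), 0L)
  expect_true(any(vapply(groupings, function(g) isTRUE(g$ambiguous),
                         logical(1))))
})
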