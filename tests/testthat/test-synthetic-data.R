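test_that("instantiate_motif honors fixed, wildcard and alternation parts", {
  withr::with_seed(31, {
    expect_equal(instantiate_motif("GHSQGE"), "GHSQGE")
    w <- instantiate_motif("xxSH")
    expect_equal(nchar(w), 4L)
    expect_equal(substr(w, 3, 4), "SH")
    for (i in 1:20) {
      expect_true(instantiate_motif("GHSI(V)GE") %in% c("GHSIGE", "GHSVGE"))
    }
    # wildcards never complete a competing diagnostic pattern
    for (i in 1:20) {
      a <- instantiate_motif("LxxxxR")
      expect_false(matches_pattern(a, "WxxxxQ"))
    }
    expect_error(instantiate_motif("xxx", residue_set = character(0)),
                 "unsatisfiable")
  })
})

test_that("generation is byte-identical for a fixed (truth, seed)", {
  b1 <- iru_bundle(seed = 42)
  b2 <- iru_bundle(seed = 42)
  expect_identical(b1$proteins, b2$proteins)
  expect_identical(b1$features, b2$features)
  expect_equal(nrow(b1$proteins), 6L)
})

test_that("different seeds change scaffolds but never truth recovery", {
  truth <- iru_truth_table()
  exp_calls <- expected_calls(truth)
  for (seed in c(1, 2, 3)) {
    bundle <- generate_assembly(truth, seed)
    got <- recovered_calls(bundle)
    expect_equal(got$at, exp_calls$at)
    expect_equal(got$kr, exp_calls$kr)
    expect_equal(got$dh, exp_calls$dh)
    expect_equal(got$ks, exp_calls$ks)
  }
  expect_false(identical(generate_assembly(truth, 1)$proteins$sequence,
                         generate_assembly(truth, 2)$proteins$sequence))
})

test_that("corrupt_bundle changes no byte outside the targeted window", {
  bundle <- iru_bundle(seed = 13)
  mutated <- corrupt_bundle(bundle, list(list(op = "at_inactivate",
                                              module = "5")))
  f <- bundle$features
  row <- f[f$module == "5" & f$kind == "AT" & f$element == "motif_II", ]
  target <- row$start + 2L   # the GHS serine byte
  for (p in seq_len(nrow(bundle$proteins))) {
    a <- strsplit(bundle$proteins$sequence[p], "")[[1]]
    b <- strsplit(mutated$proteins$sequence[p], "")[[1]]
    changed <- which(a != b)
    if (bundle$proteins$id[p] == row$protein_id) {
      expect_equal(changed, target)
      expect_equal(b[target], "G")
    } else {
      expect_length(changed, 0L)
    }
  }
})

test_that("named corruptions flip the implied downstream calls", {
  bundle <- iru_bundle(seed = 17)
  mutated <- corrupt_bundle(bundle, list(
    list(op = "at_inactivate", module = "3"),
    list(op = "ks_to_loading", module = "1"),
    list(op = "dh_lose_yxy", module = "6")))
  got <- recovered_calls(mutated)
  exp_calls <- expected_calls(mutated$truth)   # updated ground truth
  expect_equal(got$at, exp_calls$at)
  expect_equal(got$ks, exp_calls$ks)
  expect_equal(got$dh, exp_calls$dh)
  expect_equal(got$at[4], "inactive")
  expect_equal(got$ks[2], "loading")
  expect_equal(got$dh[7], "inactive")
  # empty operation list leaves the bundle unchanged
  expect_identical(corrupt_bundle(bundle, list()), bundle)
  expect_error(corrupt_bundle(bundle, list(list(op = "nope", module = "1"))),
               "unknown mutation")
})

test_that("random truth tables round-trip at mutation rate zero", {
  withr::with_seed(53, {
    for (i in 1:10) {
      truth <- random_truth_table()
      bundle <- generate_assembly(truth, seed = sample.int(1e6, 1))
      got <- recovered_calls(bundle)
      exp_calls <- expected_calls(truth)
      expect_equal(got$at, exp_calls$at)
      expect_equal(got$kr, exp_calls$kr)
      expect_equal(got$dh, exp_calls$dh)
      expect_equal(got$ks, exp_calls$ks)
      expect_equal(got$er, exp_calls$er)
    }
  })
})
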