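test_that("classify_at applies the printed motif rules", {
  expect_equal(classify_at("AVDVVQ", "GHSQGE", "LASH")$specificity,
               "methylmalonyl")
  expect_equal(classify_at("ATAYTQ", "GHSVGE", "LAFN")$specificity, "malonyl")
  expect_equal(classify_at("ATAYTQ", "GHSIGE", "LAFN")$specificity, "malonyl")
  # catalytic serine lost (GHS -> GHG) in a recognizable motif-II frame
  expect_equal(classify_at("AAAAAA", "GHGQGE", "LASH")$specificity, "inactive")
  # nothing recognizable at all
  expect_equal(classify_at("AAAAAA", "AAAAAA", "AAAA")$specificity,
               "unclassified")
  expect_error(classify_at("AVDVVQ", "GHS", "LASH"), "motif_II")
})

test_that("classify_kr applies LDD-family, subtype and A-type rules", {
  expect_equal(classify_kr("LDD", "YAA", "LAAAAR")$stereotype, "B1")
  expect_equal(classify_kr("LDD", "YCP", "LAAAAR")$stereotype, "B2")
  expect_equal(classify_kr("VDD", "YAA", "LAAAAR")$stereotype, "B1")
  expect_equal(classify_kr("IDD", "YCP", "LAAAAR")$stereotype, "B2")
  expect_equal(classify_kr("ADA", "LRG", "WAAAAQ")$stereotype, "A")
  # B without a subtype window
  expect_equal(classify_kr("LDD", "ARA", "LAAAAR")$stereotype, "B_unsubtyped")
  # contradictory evidence calls B with a conflict flag, never silently
  conflict <- classify_kr("LDD", "YAA", "WAAAAQ")
  expect_equal(conflict$stereotype, "B1")
  expect_true("conflict" %in% conflict$flags)
  # no diagnostic motif either way: explicit low-confidence fallback
  fallback <- classify_kr("GRE", "LRG", "LAAAAR")
  expect_equal(fallback$stereotype, "B_unsubtyped")
  expect_true("no_diagnostic_motif" %in% fallback$flags)
})

test_that("classify_dh applies catalytic-motif, YxY and EI rules", {
  expect_equal(classify_dh("HAAAAAAAAP", "YAY", "DAAAQ")$status, "active")
  d <- classify_dh("HAAAAAAAAP", "AAY", "DAAAQ")
  expect_equal(d$status, "inactive")      # YxY tyrosine lost
  expect_false(d$ei_candidate)
  ei <- classify_dh("HAAAAAAAAL", "YAY", "DAAAQ")
  expect_equal(ei$status, "active")
  expect_true(ei$ei_candidate)
  expect_true(classify_dh("HAAAAAAAAP", "YAY", "DAAAV")$ei_candidate)
  expect_equal(classify_dh("AAAAAAAAAP", "YAY", "DAAAQ")$status, "inactive")
})

test_that("classify_ks distinguishes loading (KSQ) from extension", {
  expect_equal(classify_ks("Q")$role, "loading")
  expect_equal(classify_ks("C")$role, "extension")
  odd <- classify_ks("A")
  expect_equal(odd$role, "extension")
  expect_true(odd$warning)
  expect_error(classify_ks(""), "single letter")
})

test_that("calls are deterministic for identical windows", {
  for (i in 1:3) {
    expect_equal(classify_at("AVDVVQ", "GHSQGE", "LASH")$specificity,
                 "methylmalonyl")
    expect_equal(classify_kr("VDD", "YAA", "LAAAAR")$stereotype, "B1")
  }
})

test_that("the iru fixture yields the printed per-module call census", {
  res <- decode_iru(seed = 42)
  labels <- vapply(res$modules, `[[`, "", "index")
  at <- vapply(res$modules, `[[`, "", "at")
  kr <- vapply(res$modules, `[[`, "", "kr")
  kr_cat <- res$calls$detail[res$calls$kind == "KR"]
  dh <- vapply(res$modules, `[[`, "", "dh")

  expect_setequal(labels[at == "methylmalonyl"],
                  c("LM", "1", "2", "3", "4", "5", "9", "10"))
  expect_setequal(labels[at == "malonyl"], c("6", "7", "8", "11"))
  expect_equal(labels[at == "inactive"], "12")

  # KR: LDD-backed B calls on M2-M4, M11; IDD/VDD on M6, M8, M9; B2 on
  # M2 and M4; A on M7
  kr_modules <- labels[kr != "absent"]
  names(kr_cat) <- kr_modules
  expect_setequal(names(kr_cat)[kr_cat == "LDD"], c("2", "3", "4", "11"))
  expect_setequal(names(kr_cat)[kr_cat %in% c("IDD", "VDD")],
                  c("6", "8", "9"))
  expect_setequal(labels[kr == "B2"], c("2", "4"))
  expect_equal(labels[kr == "A"], "7")
  expect_setequal(labels[kr == "B_unsubtyped"], c("1", "5", "10"))

  expect_setequal(labels[dh == "inactive"], c("5", "10", "12"))
  # DH11 keeps the canonical proline motif: no EI candidacy from sequence
  m11 <- res$modules[[match("11", labels)]]
  expect_false(m11$dh_ei_candidate)
})

test_that("mutating only the motif-II serine flips exactly that AT call", {
  bundle <- iru_bundle(seed = 42)
  before <- recovered_calls(bundle)
  mutated <- corrupt_bundle(bundle, list(list(op = "at_inactivate",
                                              module = "3")))
  after <- recovered_calls(mutated)
  expect_equal(after$at[4], "inactive")       # row 4 = module M3 (after LM)
  expect_equal(before$at[-4], after$at[-4])
  expect_equal(before$kr, after$kr)
  expect_equal(before$dh, after$dh)
  expect_equal(before$ks, after$ks)
})
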