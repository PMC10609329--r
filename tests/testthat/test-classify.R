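uniform_profile <- function(W, name = "flat", category = "Other") {
  em <- matrix(0, W, 20, dimnames = list(NULL, c(
    "A","C","D","E","F","G","H","I","K","L",
    "M","N","P","Q","R","S","T","V","W","Y")))
  structure(list(name = name, category = category, meth_type = "none",
                 emission = em, match_cols = seq_len(W),
                 background = rep(1 / 20, 20), length = W),
            class = "profile_model")
}

test_that("profile building selects match columns and scores conservation", {
  msa <- Biostrings::AAStringSet(c(a = "ACDEF", b = "ACDEF"))
  p <- build_profile(msa, "p", "IIM", "m6A")
  expect_equal(p$match_cols, 1:5)
  obs <- strsplit("ACDEF", "")[[1]]
  for (i in 1:5) {
    expect_equal(names(which.max(p$emission[i, ])), obs[i])
  }
  # a column with 3 gaps in 4 rows is excluded
  msa2 <- Biostrings::AAStringSet(c(a = "A-CD", b = "A-CD", c = "AACD",
                                    d = "A-CD"))
  p2 <- build_profile(msa2, "p2", "IIM")
  expect_equal(p2$match_cols, c(1L, 3L, 4L))
  expect_error(build_profile(Biostrings::AAStringSet(c(a = "ACD", b = "AC")),
                             "x", "IIM"), "ragged")
  expect_error(build_profile(Biostrings::AAStringSet(c(a = "ACD")),
                             "x", "IIM"), ">= 2")
})

test_that("window scoring matches self-score and the enumeration oracle", {
  msa <- Biostrings::AAStringSet(c(a = "MKVLAWDE", b = "MKVLAWDE"))
  p <- build_profile(msa, "self", "IIM")
  expect_equal(score_profile(p, "MKVLAWDE"),
               sum(apply(p$emission, 1, max)))
  # zero-information profile scores 0 against anything
  flat <- uniform_profile(4)
  expect_equal(score_profile(flat, "MKVLAWDE"), 0)
  # empty overlap: sequence shorter than the profile
  expect_equal(score_profile(p, "MKV"), -Inf)
  # 3-column profile against a 5-residue sequence: all 3 placements
  withr::with_seed(5, {
    msa3 <- Biostrings::AAStringSet(c(a = random_protein(3),
                                      b = random_protein(3)))
    p3 <- build_profile(msa3, "tiny", "IIM")
    for (i in 1:20) {
      s <- random_protein(5)
      expect_equal(score_profile(p3, s), oracle_window_score(p3$emission, s))
    }
  })
})

test_that("classification recovers planted categories and applies tie rules", {
  fs <- family_spec("fam1", "sporadic", category = "IIM", meth_type = "m4C",
                    divergence = 0.15)
  out <- emit_family_sequences(fs, 10, seed = 6)
  lib <- default_profile_library(seed = 50)
  lib$fam1 <- build_profile(out$aligned[1:8], "fam1", "IIM", "m4C")
  call <- classify_gene(as.character(out$seqs[[9]]), lib, threshold = 20)
  expect_equal(call$category, "IIM")
  expect_equal(call$meth_type, "m4C")
  expect_false(call$below_threshold)
  # a random sequence against an informative library is Other
  withr::with_seed(8, {
    rnd <- classify_gene(random_protein(250), lib, threshold = 20)
    expect_equal(rnd$category, "Other")
    expect_equal(rnd$meth_type, "none")
    expect_true(rnd$below_threshold)
  })
  # exact tie: the lexicographically first profile name wins with margin 0
  msa <- Biostrings::AAStringSet(c(a = "MKVLAWDEMKVL", b = "MKVLAWDEMKVL"))
  twin_lib <- list(build_profile(msa, "zeta", "IIM", "m6A"),
                   build_profile(msa, "alpha", "IIIM", "m6A"))
  tie <- classify_gene("MKVLAWDEMKVL", twin_lib, threshold = 0)
  expect_equal(tie$profile, "alpha")
  expect_equal(tie$margin, 0)
  expect_error(classify_gene("MKVL", list(), 10), "empty")
})

test_that("centroid classification propagates to cluster members", {
  fs <- family_spec("famZ", "sporadic", category = "IIIM", meth_type = "m6A",
                    divergence = 0.1)
  out <- emit_family_sequences(fs, 6, seed = 16)
  lib <- list(famZ = build_profile(out$aligned[1:4], "famZ", "IIIM", "m6A"))
  cl <- greedy_cluster(out$seqs, 0.30)
  calls <- classify_genes(out$seqs, lib, threshold = 10, clusters = cl)
  expect_equal(nrow(calls), 6L)
  expect_true(all(calls$category == "IIIM"))
})

test_that("methylation-type assignment follows the library configuration", {
  lib <- default_profile_library(seed = 42)
  expect_equal(assign_meth_type("b1a", lib), "m6A")
  expect_equal(assign_meth_type("lmoa118-like", lib), "m6A")
  expect_equal(assign_meth_type("nru-like", lib), "m6A")
  expect_equal(assign_meth_type("b3", lib), "m4C")
  expect_equal(assign_meth_type("iir-dpnii", lib), "none")
  expect_error(assign_meth_type("no-such-profile", lib), "unknown")
  # every MTase-category profile carries exactly one methylated base
  mtase <- Filter(function(p) p$category %in% c("IM", "IIM", "IIG", "IIIM", "M"),
                  lib)
  types <- vapply(mtase, `[[`, "", "meth_type")
  expect_true(all(types %in% c("m6A", "m4C", "m5C")))
})

test_that("fused MTase domains are detected as disjoint windows", {
  fa <- emit_family_sequences(
    family_spec("mtA", "sporadic", category = "IIM", meth_type = "m6A",
                ancestor_length = 150L, divergence = 0.1), 4, seed = 21)
  fb <- emit_family_sequences(
    family_spec("mtB", "sporadic", category = "IIM", meth_type = "m5C",
                ancestor_length = 150L, divergence = 0.1), 4, seed = 22)
  lib <- list(build_profile(fa$aligned, "mtA", "IIM", "m6A"),
              build_profile(fb$aligned, "mtB", "IIM", "m5C"))
  fusion <- paste0(fa$ancestor, fb$ancestor)
  res <- detect_fused_domains(fusion, lib, threshold = 50)
  expect_equal(nrow(res$hits), 2L)
  expect_true(res$fused)
  expect_true(res$hits$end[1] < res$hits$start[2])  # disjoint windows
  single <- detect_fused_domains(fa$ancestor, lib, threshold = 50)
  expect_equal(nrow(single$hits), 1L)
  expect_false(single$fused)
  withr::with_seed(9, {
    null <- detect_fused_domains(random_protein(300), lib, threshold = 50)
    expect_equal(nrow(null$hits), 0L)
    expect_false(null$fused)
  })
})
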