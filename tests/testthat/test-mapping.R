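test_that("candidate enumeration is exhaustive for small pools and seeded otherwise", {
  alpha <- agl_alphabet(list(a = c(60, 62)))
  cands <- candidate_mappings(alpha, pool = c(70, 71, 72), limit = 100)
  expect_equal(nrow(cands), 6L)                        # P(3,2) injections
  expect_true(attr(cands, "exhaustive"))
  expect_false(anyDuplicated(apply(cands, 1, paste, collapse = ",")) > 0)

  # identity mapping is present when the pool equals the source
  alpha3 <- mini_alphabet()
  cands <- candidate_mappings(alpha3, pool = alpha3$pitch_set, limit = 1000)
  expect_true(any(apply(cands, 1, function(r)
    all(r == alpha3$pitch_set))))

  # sampling fallback: exactly `limit` distinct rows, reproducible
  big <- agl_alphabet(list(a = c(60, 61), b = c(62, 63), c = c(64, 65)))
  s1 <- candidate_mappings(big, pool = 55:75, limit = 10, seed = 5)
  s2 <- candidate_mappings(big, pool = 55:75, limit = 10, seed = 5)
  expect_equal(nrow(s1), 10L)
  expect_false(attr(s1, "exhaustive"))
  expect_identical(unclass(s1), unclass(s2))
  expect_false(anyDuplicated(apply(s1, 1, paste, collapse = ",")) > 0)
  expect_true(all(apply(s1, 1, function(r) max(r) - min(r)) <= 15))

  expect_error(candidate_mappings(alpha, pool = c(0, 50, 100), span = 15),
               "span")
})

test_that("mapping application substitutes pointwise and preserves structure", {
  m <- structure(c(`60` = 70L, `64` = 65L), class = "agl_mapping")
  expect_equal(apply_mapping(m, list(c(60, 64, 60)))[[1]], c(70L, 65L, 70L))
  ident <- structure(c(`60` = 60L, `64` = 64L), class = "agl_mapping")
  expect_equal(apply_mapping(ident, list(c(60, 64, 64)))[[1]], c(60L, 64L, 64L))
  expect_error(apply_mapping(m, list(c(60, 99))), "domain")
  # injectivity: distinct-pitch count preserved
  stim <- list(c(60, 64, 60, 64), c(64, 60, 60))
  mapped <- apply_mapping(m, stim)
  expect_equal(lapply(mapped, function(x) length(unique(x))),
               lapply(stim, function(x) length(unique(x))))
})

test_that("vectorized mapping scores equal direct per-mapping recomputation", {
  alpha <- mini_alphabet()
  g <- fixture_grammar()
  stim <- lapply(list(c("a", "b", "c"), c("b", "a"), c("c", "c", "a")),
                 realize_pitches, alphabet = alpha)
  cands <- candidate_mappings(alpha, pool = c(60, 62, 64, 65, 67), limit = 1e5)
  sc <- score_mappings(cands, stim)
  cfg <- narmour_config()
  raw_direct <- t(vapply(seq_len(nrow(cands)), function(i) {
    m <- stats::setNames(as.integer(cands[i, ]), alpha$pitch_set)
    class(m) <- "agl_mapping"
    set_profile(apply_mapping(m, stim), cfg)
  }, numeric(6)))
  raw_fast <- as.matrix(sc[paste0("raw_", c("rd", "rr", "id", "pr", "cl", "co"))])
  expect_equal(unname(raw_fast), unname(raw_direct), tolerance = 1e-12)
  # z columns: population z of the raw columns, summing to zero
  for (f in c("rd", "rr", "id", "pr", "cl", "co")) {
    x <- raw_direct[, f]
    s <- sqrt(mean((x - mean(x))^2))
    zo <- if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    expect_equal(sc[[paste0("z_", f)]], zo, tolerance = 1e-10)
    expect_equal(sum(sc[[paste0("z_", f)]]), 0, tolerance = 1e-8)
  }
  expect_equal(sc$total,
               unname(rowSums(as.matrix(sc[paste0("z_", c("rd", "rr", "id",
                                                          "pr", "cl", "co"))]))))
  # two-candidate population: z components are +/-1 or 0
  sc2 <- score_mappings(structure(cands[1:2, ], source = attr(cands, "source"),
                                  exhaustive = TRUE,
                                  class = c("agl_mappings", "matrix")),
                        stim)
  z2 <- as.matrix(sc2[paste0("z_", c("rd", "rr", "id", "pr", "cl", "co"))])
  expect_true(all(abs(abs(z2) - 1) < 1e-9 | abs(z2) < 1e-9))
  expect_error(score_mappings(structure(cands[1, , drop = FALSE],
                                        source = attr(cands, "source"),
                                        exhaustive = TRUE,
                                        class = c("agl_mappings", "matrix")),
                              stim), "at least 2")
})

test_that("selection takes the extremal total with deterministic tie-breaks", {
  alpha <- mini_alphabet()
  stim <- list(realize_pitches(c("a", "b", "c", "a"), alpha))
  cands <- candidate_mappings(alpha, pool = c(58, 60, 62, 64, 65, 67), limit = 1e5)
  sc <- score_mappings(cands, stim)
  worst <- select_mapping(sc, "most_inconsistent")
  best <- select_mapping(sc, "most_consistent")
  expect_equal(attr(worst, "total"), min(sc$total))
  expect_equal(attr(best, "total"), max(sc$total))
  expect_equal(attr(worst, "rank_index"), which.min(sc$total))
  rep <- mapping_report(sc, "most_inconsistent", top = 10)
  expect_equal(nrow(rep), 10L)
  expect_equal(rep$total, sort(sc$total)[1:10])
})

test_that("the inconsistent mapping flattens proximity and widens intervals on the fixture set", {
  g <- fixture_grammar()
  set <- assemble_test_set(g, seed = 3)
  stim <- lapply(set$stimuli, `[[`, "pitches")
  res <- optimize_mapping(g$alphabet, stim, limit = 5000, seed = 3)
  mapped <- apply_mapping(res$mapping, stim)
  expect_lte(max(unlist(mapped)) - min(unlist(mapped)), 15)
  expect_lt(set_profile(mapped)["pr"], set_profile(stim)["pr"])
  expect_gt(mean(abs(unlist(lapply(mapped, diff)))),
            mean(abs(unlist(lapply(stim, diff)))))

  # direction sanity over the exhaustive permutation population: the
  # consistent selection beats the identity, which beats the inconsistent
  # selection, and proximity orders the same way
  cands <- candidate_mappings(g$alphabet, pool = g$alphabet$pitch_set,
                              limit = 50000)
  sc <- score_mappings(cands, stim)
  ident_row <- which(apply(cands, 1, function(r) all(r == g$alphabet$pitch_set)))
  best <- select_mapping(sc, "most_consistent")
  worst <- select_mapping(sc, "most_inconsistent")
  expect_gt(attr(best, "total"), sc$total[ident_row])
  expect_gt(sc$total[ident_row], attr(worst, "total"))
  # the inconsistent selection flattens proximity relative to the identity
  expect_lt(set_profile(apply_mapping(worst, stim))["pr"],
            set_profile(stim)["pr"])
  # ... and the identity still sits in the upper half of the ranking
  expect_lte(rank(-sc$total)[ident_row], 0.5 * nrow(cands))
})
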