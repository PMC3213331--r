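cfg <- hfactor_config()

test_that("secondary-structure agreement score follows the per-column penalty rule", {
  # all columns agree, no gaps: only the offset b1 = 0.9 remains
  aln <- pair_alignment("ACDEF", "ACDEF")
  pred <- ss_prediction(c("H", "H", "C", "S", "C"), rep(5L, 5))
  obs <- ss_assignment(c("H", "H", "C", "S", "C"))
  expect_equal(score1(pred, obs, aln, cfg), 0.9)

  # every column gapped on one side: f = 1 everywhere -> a1 + b1 = 2.2
  aln2 <- pair_alignment("AC---", "--AGT")
  pred2 <- ss_prediction(c("H", "H"), c(5L, 5L))
  obs2 <- ss_assignment(c("C", "C", "C"))
  expect_equal(score1(pred2, obs2, aln2, cfg), 2.2)

  # 10 columns: 5 matches, 5 mismatches with confidence 4 ->
  # 1.3 * (5*5/10) + 0.9 = 4.15
  aln3 <- pair_alignment(strrep("A", 10), strrep("G", 10))
  pred3 <- ss_prediction(c(rep("H", 5), rep("S", 5)), rep(4L, 10))
  obs3 <- ss_assignment(c(rep("H", 5), rep("C", 5)))
  expect_equal(score1(pred3, obs3, aln3, cfg), 4.15)
})

test_that("score 1 walks prediction and assignment by their own ungapped positions", {
  # target has a gap: prediction index must not advance there
  aln <- pair_alignment("AC-DE", "ACGDE")
  pred <- ss_prediction(c("H", "S", "C", "C"), rep(2L, 4))
  obs <- ss_assignment(c("H", "S", "H", "C", "C"))
  # columns: match, match, gap (f=1), match, match -> 1.3*(1/5) + 0.9
  expect_equal(score1(pred, obs, aln, cfg), 1.3 / 5 + 0.9)
  # coverage mismatch errors
  expect_error(score1(ss_prediction("H", 1L), obs, aln, cfg), "covers")
})

test_that("identity score counts identical non-gap, non-X columns over N", {
  expect_equal(score2(pair_alignment("ACDEFGHIKL", "ACDEFGHIKL")), 0)
  expect_equal(score2(pair_alignment("ACDEFGHIKL", "GHIKLACDEF")), 10)
  expect_equal(score2(pair_alignment("ACDEFGHIKL", "ACDEFAAAAA")), 5.0)
  # case-insensitive; X never matches, including X-X
  expect_equal(score2(pair_alignment("acd", "ACD")), 0)
  expect_equal(score2(pair_alignment("XXA", "XXA")), 10 * (1 - 1 / 3))
  # gaps count as non-identity but stay in N
  expect_equal(score2(pair_alignment("AC-D", "ACED")), 10 * (1 - 3 / 4))
})

test_that("identity score agrees exactly with a brute-force column count on random alignments", {
  set.seed(1234)
  letters_pool <- c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], "-")
  for (i in 1:300) {
    n <- sample(5:40, 1)
    tc <- sample(letters_pool, n, replace = TRUE)
    mc <- sample(letters_pool, n, replace = TRUE)
    both <- tc == "-" & mc == "-"
    mc[both] <- "A"
    aln <- pair_alignment(paste(tc, collapse = ""), paste(mc, collapse = ""))
    expect_equal(score2(aln), brute_score2(aln$target, aln$template))
  }
})

test_that("identity score strictly decreases as identities are added at fixed N", {
  n <- 20
  vals <- vapply(0:n, function(k) {
    tc <- rep("A", n)
    mc <- c(rep("A", k), rep("G", n - k))
    score2(pair_alignment(paste(tc, collapse = ""), paste(mc, collapse = "")))
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("heterogeneity score maps spread affinely with the published anchors", {
  expect_equal(score3(cfg = cfg, spread = 0.1), 1.0, tolerance = 1e-12)
  expect_equal(score3(cfg = cfg, spread = 7), 9.97)     # near the 10 anchor
  expect_equal(score3(cfg = cfg, spread = 0), 0.87)     # offset at zero
  expect_equal(score3(cfg = cfg, spread = 8), 10)       # clamp binds
  nocl <- hfactor_config(clamp = FALSE)
  expect_equal(score3(cfg = nocl, spread = 8), 1.3 * 8 + 0.87)
  # identical models: spread 0 -> 0.87
  x <- random_structure(12)
  ens <- model_ensemble(lapply(1:3, function(i) { m <- x; m$label <- paste0("m", i); m }))
  expect_equal(score3(ens, cfg), 0.87, tolerance = 1e-9)
})

test_that("domain score maps the mean domain cRMS with the published anchors", {
  # fragment identical to its sole reference: offset b4 = 0.87
  set.seed(99)
  frag <- random_structure(20, label = "frag")
  refs <- domain_reference_set(list(PF1 = list(
    list(structure = frag, sequence = ca_sequence(frag)))))
  hit <- domain_hit("PF1", 1, 20, 1e-30)
  expect_equal(score4(frag, list(hit), refs, cfg), 0.87, tolerance = 1e-9)

  # planted mean cRMS 2.79 -> 4.50, and 3.03 -> 4.81 (reported 4.8)
  dc <- make_domain_case(fixture_spec(seed = 21, n_residues = 40), 2.79)
  expect_equal(round(score4(dc$ma, dc$hits, dc$refs, cfg), 1), 4.5)
  dc2 <- make_domain_case(fixture_spec(seed = 22, n_residues = 40), 3.03)
  expect_equal(round(score4(dc2$ma, dc2$hits, dc2$refs, cfg), 1), 4.8)
})

test_that("aggregation reproduces published worked examples and the /20 mode", {
  expect_identical(aggregate_scores(list(s1 = 1.1, s2 = 8.6, s3 = 2.9,
                                         s4 = 3.8))$h_percent_rounded, 41L)
  expect_identical(aggregate_scores(list(s1 = 7.0, s2 = 8.1, s3 = 7.5,
                                         s4 = 7.5))$h_percent_rounded, 75L)
  # structure-only mode ignores a computed score 1, as in the NMR protocol
  expect_identical(aggregate_scores(list(s1 = 1.03, s2 = NA, s3 = 2.13,
                                         s4 = 3.43),
                                    mode = "structure_only")$h_percent_rounded,
                   28L)
  expect_error(aggregate_scores(list(s1 = NA, s2 = NA, s3 = NA, s4 = NA)),
               "no available")
})

test_that("aggregation equals the brute-force mean over every availability pattern", {
  vals <- c(s1 = 2.5, s2 = 7.1, s3 = 0.9, s4 = 9.3)
  for (mask in 1:15) {
    avail <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    s <- ifelse(avail, vals, NA_real_)
    agg <- aggregate_scores(as.list(setNames(s, names(vals))))
    expect_equal(agg$h_percent, 100 * mean(s[avail]) / 10)
  }
})

test_that("increasing any single component score never decreases the aggregate", {
  base <- list(s1 = 3, s2 = 4, s3 = 5, s4 = 6)
  h0 <- aggregate_scores(base)$h_percent
  for (k in names(base)) for (d in c(0.5, 2)) {
    up <- base
    up[[k]] <- up[[k]] + d
    expect_gte(aggregate_scores(up)$h_percent, h0)
  }
})

test_that("component scores stay in [0,10] and aggregates in [0,100] under clamping", {
  set.seed(77)
  for (i in 1:20) {
    spread <- runif(1, 0, 12)
    s3v <- score3(cfg = cfg, spread = spread)
    expect_gte(s3v, 0); expect_lte(s3v, 10)
  }
  ssp <- make_ss_pair(fixture_spec(seed = 31, n_residues = 40,
                                   ss_agreement = 0, confidence = 10L))
  s1v <- score1(ssp$pred, ssp$obs, ssp$alignment, cfg)
  expect_gte(s1v, 0); expect_lte(s1v, 10)
})

test_that("the full computation runs every available score and flags the mode", {
  spec <- fixture_spec(seed = 55, n_models = 6, n_residues = 40,
                       target_spread = 0.6, identity_fraction = 0.3,
                       ss_agreement = 0.9)
  fx <- make_ensemble(spec)
  aln <- make_alignment(spec)
  # an ungapped alignment over the model sequence keeps coverage consistent
  ssp <- make_ss_pair(spec)
  h_struct <- hfactor(fx$ensemble)
  expect_identical(h_struct$mode, "structure_only")
  expect_true(is.na(h_struct$scores$s1))
  expect_true(is.na(h_struct$scores$s2))
  expect_equal(h_struct$h_percent, 10 * h_struct$scores$s3)

  h_part <- hfactor(fx$ensemble, alignment = aln)
  expect_identical(h_part$mode, "partial")
  expect_equal(h_part$scores$s2, attr(aln, "expected_score2"))

  h_seq <- hfactor(fx$ensemble, alignment = ssp$alignment,
                   ss_pred = ssp$pred, ss_assign = ssp$obs)
  expect_equal(h_seq$scores$s1, ssp$expected_score1)
  expect_false(is.na(h_seq$scores$s3))
})

test_that("a single model is rejected with the ensemble requirement", {
  x <- random_structure(10)
  single <- structure(list(models = list(x), n = 1L),
                      class = "model_ensemble")
  expect_error(hfactor(single), "single model")
})

test_that("hfactor methods expose scores, aggregate and spread", {
  fx <- make_ensemble(fixture_spec(seed = 3, n_models = 4, n_residues = 30,
                                   target_spread = 0.4))
  h <- hfactor(fx$ensemble)
  co <- coef(h)
  expect_named(co, c("s1", "s2", "s3", "s4", "h_percent"))
  expect_equal(unname(co["s3"]), h$scores$s3)
  expect_output(print(h), "H-factor")
  expect_output(summary(h), "spread")
  pf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pf)
  expect_silent(plot(h))
  grDevices::dev.off()
})

test_that("config files in key=value and JSON forms round-trip", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "a3 = 1.5", "clamp = false",
               "max_fragments = 3"), f)
  cfg2 <- read_hfactor_config(f)
  expect_equal(cfg2$a3, 1.5)
  expect_false(cfg2$clamp)
  expect_identical(cfg2$max_fragments, 3L)
  expect_equal(cfg2$a1, 1.3)   # untouched default

  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"b3": 0.9, "evalue_cutoff": 1e-5}', fj)
  cfg3 <- read_hfactor_config(fj)
  expect_equal(cfg3$b3, 0.9)
  expect_equal(cfg3$evalue_cutoff, 1e-5)
  fu <- withr::local_tempfile(fileext = ".cfg")
  writeLines("nope = 1", fu)
  expect_error(read_hfactor_config(fu), "unknown config key")
})
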