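test_that("GFP is the population spatial standard deviation", {
  ep <- eeg_epochs(array(c(1, -1), dim = c(2, 1, 1)), 125, c("a", "b"),
    reference = "average"
  )
  expect_equal(compute_gfp(ep)$gfp, 1)
  flat <- eeg_epochs(array(0, dim = c(2, 3, 1)), 125, c("a", "b"),
    reference = "average"
  )
  expect_equal(compute_gfp(flat)$gfp, rep(0, 3))
  # homogeneity
  arr <- array(rnorm(19 * 50), dim = c(19, 50, 1))
  ep1 <- average_reference(eeg_epochs(arr, 125, mont19$channel))
  ep3 <- average_reference(eeg_epochs(arr * 3, 125, mont19$channel))
  expect_equal(compute_gfp(ep3)$gfp, 3 * compute_gfp(ep1)$gfp, tolerance = 1e-12)
  # refuses non-referenced input
  expect_error(compute_gfp(eeg_epochs(arr, 125, mont19$channel)), "average")
})

test_that("GFP peaks are strict interior maxima, one per plateau", {
  map <- canonical_maps(mont19)$maps[, "A"]
  # rectified sinusoid: 2 peaks per 10 Hz cycle over 2 s ~ 40 peaks
  t <- (seq_len(250) - 1) / 125
  ep <- map_epochs(map, sin(2 * pi * 10 * t))
  pk <- extract_gfp_peaks(ep)
  expect_gte(ncol(pk$maps), 38)
  expect_lte(ncol(pk$maps), 42)
  # monotone GFP has no peaks
  mono <- map_epochs(map, seq(0.1, 1, length.out = 100))
  expect_equal(ncol(extract_gfp_peaks(mono)$maps), 0)
  # plateau counts once, at its first sample
  plat <- map_epochs(map, c(0.1, 0.5, 1, 1, 1, 0.5, 0.1, 0.1))
  pkp <- extract_gfp_peaks(plat)
  expect_equal(ncol(pkp$maps), 1)
  expect_equal(pkp$index$sample, 3)
  # epoch boundaries are never peaks
  edge <- map_epochs(map, c(1, 0.5, 0.2, 0.5, 1))
  expect_equal(ncol(extract_gfp_peaks(edge)$maps), 0)
})

test_that("T-AAHC with k equal to the number of maps is the identity", {
  tpl <- orthogonal_templates()
  res <- taahc_cluster(tpl$maps, k = 4)
  expect_equal(ncol(res$maps), 4)
  expect_equal(sort(attr(res, "assignment")), 1:4)
  for (j in 1:4) {
    best <- max(abs(cor(res$maps[, j], tpl$maps)))
    expect_gt(best, 0.999)
  }
})

test_that("T-AAHC recovers planted templates from polarity-flipped copies", {
  tpl <- orthogonal_templates()
  set.seed(5)
  idx <- rep(1:4, each = 100)
  maps <- tpl$maps[, idx] * rep(sample(c(-1, 1), 400, TRUE), each = 19)
  res <- taahc_cluster(maps, k = 4)
  cc <- abs(cor(res$maps, tpl$maps))
  expect_equal(unname(apply(cc, 2, max)), rep(1, 4), tolerance = 1e-9)
  # recovered assignment groups the copies correctly
  asg <- attr(res, "assignment")
  expect_equal(length(unique(asg[idx == 2])), 1)
})

test_that("T-AAHC is invariant to polarity flips and positive rescaling", {
  tpl <- orthogonal_templates()
  set.seed(6)
  idx <- rep(1:4, each = 60)
  base <- tpl$maps[, idx] + matrix(rnorm(19 * 240, sd = 0.15), 19)
  flip <- rep(sample(c(-1, 1), 240, TRUE), each = 19)
  scl <- rep(runif(240, 0.5, 2), each = 19)
  r1 <- taahc_cluster(base, k = 4, weights = rep(1, 240))
  r2 <- taahc_cluster(base * flip * scl, k = 4, weights = rep(1, 240))
  expect_equal(attr(r1, "assignment"), attr(r2, "assignment"))
  cc <- abs(cor(r1$maps, r2$maps))
  expect_equal(unname(apply(cc, 2, max)), rep(1, 4), tolerance = 1e-9)
})

test_that("labeling maximizes total correlation and recovers permutations", {
  canon <- canonical_maps(mont19)
  self <- label_prototypes(canon, canon)
  expect_equal(self$labels, c("A", "B", "C", "D"))
  expect_equal(attr(self, "label_total_corr"), 4, tolerance = 1e-12)
  expect_equal(attr(self, "label_mapping")$map_index, 1:4)
  # shuffled input: the inverse permutation is recovered
  perm <- c(3, 1, 4, 2)
  shuffled <- prototype_set(canon$maps[, perm], canon$channels, source = "group")
  lab <- label_prototypes(shuffled, canon)
  expect_equal(attr(lab, "label_mapping")$map_index, order(perm))
  expect_equal(unname(lab$maps), unname(canon$maps))
  # bijection for arbitrary non-degenerate prototypes
  tpl <- orthogonal_templates()
  lab2 <- label_prototypes(tpl, canon)
  expect_setequal(attr(lab2, "label_mapping")$map_index, 1:4)
})

test_that("back-fitting assigns prototypes polarity-invariantly with fit 1", {
  canon <- canonical_maps(mont19)
  epA <- map_epochs(canon$maps[, "A"], rep(1, 50))
  sA <- backfit(epA, canon)
  expect_true(all(sA$label == "A"))
  expect_equal(sA$fit, rep(1, 50), tolerance = 1e-9)
  epB <- map_epochs(canon$maps[, "B"], rep(-1, 50))
  expect_true(all(backfit(epB, canon)$label == "B"))
})

test_that("zero-variance samples inherit the nearest label and are counted", {
  canon <- canonical_maps(mont19)
  ep <- map_epochs(canon$maps[, "C"], c(1, 1, 0, 0, 1, 1))
  s <- backfit(ep, canon)
  expect_equal(attr(s, "n_zero_variance"), 2L)
  expect_true(all(s$label == "C"))
  expect_true(all(is.na(s$fit[3:4])))
})

test_that("parameters follow the counting rules on a hand-built sequence", {
  canon <- canonical_maps(mont19)
  labs <- c(rep("A", 50), rep("B", 50), rep("A", 50), rep("C", 50), rep("D", 50))
  arr <- array(canon$maps[, labs], dim = c(19, 250, 1))
  ep <- average_reference(eeg_epochs(arr, 125, mont19$channel))
  s <- backfit(ep, canon)
  expect_equal(s$label, labs)
  par <- compute_parameters(s)
  expect_equal(par$coverage_pct, c(40, 20, 20, 20))
  # first A and last D are truncated: duration from complete runs only
  expect_equal(par$duration_ms[par$class == "A"], 400)
  expect_equal(par$duration_ms[par$class == "B"], 400)
  expect_equal(par$duration_ms[par$class == "C"], 400)
  expect_true(is.na(par$duration_ms[par$class == "D"]))
  expect_equal(par$occurrence_per_s, c(0.5, 0.5, 0.5, 0))
  expect_equal(sum(par$coverage_pct), 100)
})

test_that("transition probabilities count segment boundaries within epochs", {
  canon <- canonical_maps(mont19)
  labs <- c(rep("A", 5), rep("B", 5), rep("A", 5), rep("C", 5))
  arr <- array(canon$maps[, labs], dim = c(19, 20, 1))
  ep <- average_reference(eeg_epochs(arr, 125, mont19$channel))
  tm <- transition_probabilities(backfit(ep, canon))
  expect_equal(tm["A", "B"], 0.5)
  expect_equal(tm["A", "C"], 0.5)
  expect_equal(tm["B", "A"], 1)
  expect_true(all(is.na(tm["D", ])))
  expect_true(all(is.na(tm["C", ]))) # last segment: no outgoing transition
  expect_equal(unname(diag(tm)[1:2]), rep(0, 2))
  # alternating two classes
  labs2 <- rep(c(rep("A", 4), rep("B", 4)), 3)
  arr2 <- array(canon$maps[, labs2], dim = c(19, 24, 1))
  tm2 <- transition_probabilities(
    backfit(average_reference(eeg_epochs(arr2, 125, mont19$channel)), canon)
  )
  expect_equal(tm2["A", "B"], 1)
  expect_equal(tm2["B", "A"], 1)
  # epoch boundaries contribute no transitions
  arr3 <- array(canon$maps[, c(rep("A", 10), rep("B", 10))], dim = c(19, 10, 2))
  tm3 <- transition_probabilities(
    backfit(average_reference(eeg_epochs(arr3, 125, mont19$channel)), canon)
  )
  expect_equal(sum(attr(tm3, "counts")), 0)
})

test_that("noiseless prototype data reproduces sequence statistics exactly", {
  spec <- tiny_spec(snr = Inf, prototype_jitter = 0)
  tr <- sample_state_sequence(spec, seed = 31)
  ep <- synthesize_eeg(tr, spec, seed = 32)
  s <- backfit(ep, attr(ep, "prototypes"))
  # exact recovery wherever the carrier is nonzero; the only zero-carrier
  # samples inherit their neighbor, which is the true label
  expect_gt(mean(s$label == tr$sequence$label), 0.999)
  est <- compute_parameters(s)
  tru <- tr$parameters
  expect_equal(est$coverage_pct, tru$coverage_pct, tolerance = 1e-6)
  expect_equal(est$occurrence_per_s, tru$occurrence_per_s, tolerance = 1e-6)
})

test_that("occurrence x duration approximates coverage when truncation is rare", {
  # long epochs so boundary-truncated runs hold a negligible time share
  spec <- microstate_spec(epoch_length_ms = 10000, n_epochs = 8)
  tr <- sample_state_sequence(spec, seed = 77)
  p <- tr$parameters
  lhs <- p$occurrence_per_s * p$duration_ms # ms of class per second
  rhs <- p$coverage_pct / 100 * 1000
  expect_lt(max(abs(lhs - rhs) / rhs), 0.1)
})

test_that("a cohort of identical subjects yields identical reports", {
  spec <- tiny_spec(prototype_jitter = 0)
  tr <- sample_state_sequence(spec, seed = 21)
  ep <- synthesize_eeg(tr, spec, seed = 22)
  cohort <- tibble::tibble(
    subject_id = c("s1", "s2"), group = "NC", age = c(70, 70),
    epochs = list(ep, ep)
  )
  res <- run_group_microstate(cohort, min_duration_ms = 16)
  expect_equal(res$reports$report[[1]]$parameters,
    res$reports$report[[2]]$parameters)
  # single-subject group degenerates gracefully
  one <- run_group_microstate(cohort[1, ], min_duration_ms = 16)
  expect_s3_class(one$prototypes, "prototype_set")
  expect_error(run_group_microstate(cohort[0, ]), "empty")
})
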