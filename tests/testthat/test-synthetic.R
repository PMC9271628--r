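test_that("spec validation enforces the dwell-time and transition contracts", {
  tm <- default_transitions("NC")
  expect_s3_class(microstate_spec(transition_matrix = tm), "microstate_spec")
  bad_diag <- tm
  bad_diag[1, 1] <- 0.1
  bad_diag[1, 2] <- bad_diag[1, 2] - 0.1
  expect_error(microstate_spec(transition_matrix = bad_diag), "diagonal")
  bad_sum <- tm
  bad_sum[2, 3] <- bad_sum[2, 3] + 0.01
  expect_error(microstate_spec(transition_matrix = bad_sum), "sum to 1")
  expect_error(microstate_spec(snr = 0), "snr")
  expect_error(microstate_spec(snr = -2), "snr")
  expect_error(
    microstate_spec(mean_duration_ms = c(A = 5, B = 80, C = 80, D = 80)),
    "2 samples"
  )
  # a one-class absorbing chain is unrepresentable: diagonal must be 0
  absorbing <- matrix(0, 4, 4)
  absorbing[, 1] <- 1
  diag(absorbing) <- c(1, 0, 0, 0)
  absorbing[1, ] <- c(1, 0, 0, 0)
  expect_error(microstate_spec(transition_matrix = absorbing), "diagonal")
})

test_that("default transition matrices are valid and encode the group contrast", {
  for (g in c("NC", "LLS")) {
    tm <- default_transitions(g)
    expect_equal(rowSums(tm), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(diag(tm)), rep(0, 4))
  }
  nc <- default_transitions("NC")
  lls <- default_transitions("LLS")
  expect_gt(lls["B", "D"], nc["B", "D"])
  expect_gt(lls["D", "B"], nc["D", "B"])
  expect_lt(lls["A", "B"], nc["A", "B"])
  expect_lt(lls["A", "C"], nc["A", "C"])
})

test_that("a forced cycle restricts realized transitions to its support", {
  cyc <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  cyc["A", "B"] <- 1
  cyc["B", "C"] <- 1
  cyc["C", "D"] <- 1
  cyc["D", "A"] <- 1
  spec <- tiny_spec(transition_matrix = cyc)
  tr <- sample_state_sequence(spec, seed = 4)
  counts <- attr(tr$transitions, "counts")
  off_cycle <- counts
  off_cycle[cbind(c("A", "B", "C", "D"), c("B", "C", "D", "A"))] <- 0
  expect_equal(sum(off_cycle), 0)
  expect_gt(sum(counts), 0)
})

test_that("realized dwell times match the gamma model at scale", {
  spec <- microstate_spec(
    mean_duration_ms = c(A = 80, B = 80, C = 80, D = 80),
    n_epochs = 40 # 80 s >= the 60 s needed for a stable mean
  )
  tr <- sample_state_sequence(spec, seed = 9)
  expect_lt(max(abs(tr$parameters$duration_ms - 80)), 10)
  # dwell-time floor: no complete (non-boundary) run shorter than 2 samples
  segs <- microdyn:::segment_table(tr$sequence)
  expect_gte(min(segs$n_samples[!segs$truncated]), 2)
})

test_that("realized coverage sums to one and sequences respect epoch geometry", {
  spec <- tiny_spec()
  tr <- sample_state_sequence(spec, seed = 12)
  expect_equal(sum(tr$parameters$coverage_pct), 100, tolerance = 1e-9)
  expect_equal(nrow(tr$sequence), 5 * 250)
  expect_equal(max(tr$sequence$sample), 250)
})

test_that("generation is seed-deterministic with distinct paths across seeds", {
  spec <- tiny_spec()
  t1 <- sample_state_sequence(spec, seed = 3)
  t2 <- sample_state_sequence(spec, seed = 3)
  t3 <- sample_state_sequence(spec, seed = 4)
  expect_identical(t1$sequence$label, t2$sequence$label)
  expect_false(identical(t1$sequence$label, t3$sequence$label))
  e1 <- synthesize_eeg(t1, spec, seed = 8)
  e2 <- synthesize_eeg(t1, spec, seed = 8)
  e3 <- synthesize_eeg(t1, spec, seed = 9)
  expect_identical(e1$data, e2$data)
  expect_false(identical(e1$data, e3$data))
  expect_equal(dim(e1$data), dim(e3$data))
})

test_that("synthesized epochs are average-referenced at the requested snr", {
  spec <- tiny_spec(snr = 5)
  tr <- sample_state_sequence(spec, seed = 14)
  ep <- synthesize_eeg(tr, spec, seed = 15)
  m <- apply(ep$data, c(2, 3), mean)
  expect_lt(max(abs(m)), 1e-9)
  expect_equal(dim(ep$data), c(19, 250, 5))
})

test_that("rank-1 noise with negligible signal drives omega to its floor", {
  spec <- tiny_spec(noise_spatial_rank = 1, snr = 1e-8, anterior_noise_rank = 0)
  tr <- sample_state_sequence(spec, seed = 25)
  ep <- synthesize_eeg(tr, spec, seed = 26)
  om <- subject_omega(ep)
  expect_lt(om$omega_global, 1.05)
  expect_gte(om$omega_global, 1)
})

test_that("the default cohort realizes the patient-control contrast", {
  coh <- generate_group_cohort(seed = 7, synthesize = FALSE)
  expect_equal(nrow(coh), 40)
  expect_true(all(coh$age >= 60 & coh$age <= 90))
  tru <- truth_outcomes(coh)
  dur <- tapply(
    tru$value[tru$measure == "duration_ms"],
    tru$group[tru$measure == "duration_ms"], mean
  )
  occ <- tapply(
    tru$value[tru$measure == "occurrence_per_s"],
    tru$group[tru$measure == "occurrence_per_s"], mean
  )
  expect_gt(dur[["LLS"]], dur[["NC"]])
  expect_lt(occ[["LLS"]], occ[["NC"]])
})

test_that("an empty cohort is returned without error", {
  nc <- nc_spec_default()
  nc$n_subjects_per_group <- 0
  lls <- lls_spec_default()
  lls$n_subjects_per_group <- 0
  coh <- generate_group_cohort(nc, lls, seed = 1)
  expect_equal(nrow(coh), 0)
})

test_that("cohorts are seed-stable and extensible without reshuffling", {
  nc <- nc_spec_default()
  nc$n_subjects_per_group <- 2
  lls <- lls_spec_default()
  lls$n_subjects_per_group <- 2
  c1 <- generate_group_cohort(nc, lls, seed = 50, synthesize = FALSE)
  c2 <- generate_group_cohort(nc, lls, seed = 50, synthesize = FALSE)
  expect_identical(c1$truth[[3]]$sequence$label, c2$truth[[3]]$sequence$label)
  nc3 <- nc
  nc3$n_subjects_per_group <- 3
  c3 <- generate_group_cohort(nc3, lls, seed = 50, synthesize = FALSE)
  expect_identical(c1$truth[[1]]$sequence$label, c3$truth[[1]]$sequence$label)
  expect_identical(c1$age[1:2], c3$age[1:2])
})

test_that("written cohorts round-trip through EDF, manifest and truth JSON", {
  nc <- nc_spec_default()
  nc$n_subjects_per_group <- 1
  nc$n_epochs <- 3
  lls <- lls_spec_default()
  lls$n_subjects_per_group <- 1
  lls$n_epochs <- 3
  coh <- generate_group_cohort(nc, lls, seed = 60)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(file.path(dir, man$edf))))
  expect_true(all(file.exists(file.path(dir, man$truth))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_edf(file.path(dir, man$edf[1]))
  expect_equal(back$sfreq, 125)
  expect_equal(back$channels, mont19$channel)
  tj <- jsonlite::read_json(file.path(dir, man$truth[1]), simplifyVector = TRUE)
  expect_equal(tj$subject_id, coh$subject_id[1])
  expect_equal(
    tj$parameters$coverage_pct,
    coh$truth[[1]]$parameters$coverage_pct,
    tolerance = 1e-9
  )
})
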