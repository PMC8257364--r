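test_that("som_activations returns Euclidean distances per unit", {
  w <- rbind(c(0, 0), c(3, 4))
  expect_equal(som_activations(c(0, 0), w), c(0, 5))
  expect_equal(som_activations(c(1, 1), rbind(c(0, 0))), sqrt(2))
  expect_equal(som_activations(c(3, 4), w)[2], 0)
  expect_error(som_activations(c(1, 2, 3), w), "dimension mismatch")
})

test_that("compete is one-hot with lowest-index tie-breaking", {
  expect_equal(compete(c(0.2, 0.1, 0.5)), c(0, 1, 0))
  expect_equal(compete(c(0.3, 0.3)), c(1, 0))
  expect_equal(compete(0.7), 1)
  for (i in 1:50) {
    set.seed(i)
    u <- compete(runif(sample(1:20, 1)))
    expect_equal(sum(u), 1)
    expect_true(all(u %in% c(0, 1)))
  }
})

test_that("som_update pulls only the neighbourhood toward the input", {
  w <- rbind(c(0, 0), c(1, 1))
  up <- som_update(c(1, 0), w, nbrs = 1L, alpha = 0.5)
  expect_equal(up[1, ], c(0.5, 0))
  expect_equal(up[2, ], c(1, 1))  # outside N: unchanged
  expect_equal(som_update(c(1, 0), w, nbrs = 1L, alpha = 1)[1, ], c(1, 0))
})

test_that("grossberg_output reads the winner's weight; outstar updates it", {
  z <- matrix(c(0.2, 0.9), nrow = 1)
  expect_equal(grossberg_output(c(0, 1), z), 0.9)
  expect_equal(grossberg_output(c(1, 0), matrix(0, 1, 2)), 0)
  expect_error(grossberg_output(c(1, 1), z), "one-hot")

  # geometric approach to the target d
  z1 <- outstar_update(c(0, 0.3), u = c(1, 0), y = 0, d = 1, gamma = 0.5)
  expect_equal(z1, c(0.5, 0.3))
  z2 <- outstar_update(z1, u = c(1, 0), y = 0.5, d = 1, gamma = 0.5)
  expect_equal(z2, c(0.75, 0.3))
  expect_equal(outstar_update(z2, c(1, 0), y = 0.75, d = 0.75, gamma = 0.5),
               z2)
})

test_that("lattice neighbourhoods match hand enumeration", {
  g <- lattice_geometry("square", "planar", 3, 3)
  expect_equal(neighborhood(5, 0, g), 5L)           # radius 0 -> winner only
  expect_setequal(neighborhood(5, 1, g), 1:9)       # Chebyshev ring covers all
  expect_setequal(neighborhood(1, 1, g), c(1L, 2L, 4L, 5L))

  ring <- lattice_geometry("square", "toroidal", 1, 5)
  expect_setequal(neighborhood(1, 1, ring), c(5L, 1L, 2L))

  # hex odd-r: (1,0)->unit 4 is adjacent to origin, (1,1)->unit 5 is not
  hexg <- lattice_geometry("hexagonal", "planar", 3, 3)
  d <- lattice_distances(hexg)
  expect_equal(d[1, 4], 1)
  expect_equal(d[1, 5], 2)
  # toroidal wrap brings opposite edges together
  hext <- lattice_geometry("hexagonal", "toroidal", 4, 4)
  dt <- lattice_distances(hext)
  expect_true(all(dt <= max(lattice_distances(
    lattice_geometry("hexagonal", "planar", 4, 4)))))
  expect_true(isSymmetric(dt))
})

test_that("training is deterministic and respects weight-range invariants", {
  coh <- two_cluster_cohort(25, seed = 3)
  sched <- training_schedule(epochs = 30)
  g <- lattice_geometry("square", "toroidal", 4, 4)
  m1 <- train_cpn(coh, c("mmse", "faq"), g, sched, seed = 11)
  m2 <- train_cpn(coh, c("mmse", "faq"), g, sched, seed = 11)
  expect_identical(m1$som$w, m2$som$w)
  expect_identical(m1$grossberg$z, m2$grossberg$z)
  expect_true(all(m1$som$w >= 0 & m1$som$w <= 1))
  expect_true(all(m1$grossberg$z >= 0 & m1$grossberg$z <= 1))
})

test_that("zero-epoch training yields a usable untrained model", {
  coh <- two_cluster_cohort(10)
  m <- train_cpn(coh, c("mmse", "faq"),
                 schedule = training_schedule(epochs = 0), seed = 2)
  expect_true(all(m$grossberg$z == 0.5))
  expect_length(cpn_score(m, coh), nrow(coh))
})

test_that("compiled trainer matches the naive loop reference bit-for-bit", {
  coh <- two_cluster_cohort(9, seed = 5)  # 18 records
  sched <- training_schedule(epochs = 7, alpha0 = 0.4, gamma0 = 0.2)
  for (g in list(lattice_geometry("square", "planar", 2, 5),
                 lattice_geometry("hexagonal", "toroidal", 3, 3))) {
    m <- train_cpn(coh, c("mmse", "faq", "gds"), g, sched, seed = 31)
    ref <- reference_train_cpn(coh, c("mmse", "faq", "gds"), g, sched,
                               seed = 31)
    expect_identical(unname(m$som$w), ref$w)
    expect_identical(m$grossberg$z, ref$z)
  }
})

test_that("single-unit readout converges to the MCI prevalence", {
  coh <- two_cluster_cohort(30, seed = 8)  # prevalence 0.5
  sched <- training_schedule(epochs = 100)
  g <- lattice_geometry("square", "planar", 1, 1)
  m <- train_cpn(coh, "faq", g, sched, seed = 21)
  oracle <- single_unit_z_oracle(coh, sched, seed = 21)
  expect_equal(m$grossberg$z, oracle, tolerance = 1e-12)
  expect_lt(abs(m$grossberg$z - mean(coh$label)), 1e-2)
})

test_that("two-unit map specializes to two well-separated clusters", {
  coh <- two_cluster_cohort(40, seed = 13)
  g <- lattice_geometry("square", "planar", 1, 2)
  m <- train_cpn(coh, c("mmse", "faq"), g,
                 training_schedule(epochs = 80, radius0 = 0), seed = 7)
  X <- apply_scaling(m$scaling, coh)
  centers <- rbind(colMeans(X[coh$label == 0, ]),
                   colMeans(X[coh$label == 1, ]))
  # each prototype sits near one cluster mean (k-means-like check)
  d <- as.matrix(dist(rbind(m$som$w, centers)))[1:2, 3:4]
  assignment <- apply(d, 1, which.min)
  expect_setequal(assignment, c(1, 2))
  expect_true(all(apply(d, 1, min) < 0.1))
  # readout columns near the cluster labels
  expect_setequal(round(m$grossberg$z), c(0, 1))
  # monotone specialization of scores
  s <- cpn_score(m, coh)
  expect_gt(mean(s[coh$label == 1]), mean(s[coh$label == 0]))
})

test_that("classification is strict at the threshold", {
  coh <- two_cluster_cohort(10)
  m <- train_cpn(coh, c("mmse", "faq"),
                 schedule = training_schedule(epochs = 0), seed = 1)
  # untrained model scores are exactly 0.5 everywhere
  expect_equal(cpn_classify(m, coh, threshold = 0.5), rep(0L, nrow(coh)))
  expect_equal(cpn_classify(m, coh, threshold = 0.49), rep(1L, nrow(coh)))
  expect_equal(cpn_classify(m, coh, threshold = 1), rep(0L, nrow(coh)))
  expect_error(set_threshold(m, 1.2), "threshold")
})

test_that("model JSON serialization round-trips predictions", {
  coh <- two_cluster_cohort(15, seed = 2)
  m <- train_cpn(coh, c("age", "mmse", "faq"),
                 lattice_geometry("hexagonal", "toroidal", 3, 4),
                 training_schedule(epochs = 20), seed = 5)
  m <- set_threshold(m, 0.37)
  path <- tempfile(fileext = ".json")
  write_cpn_model(m, path)
  back <- read_cpn_model(path)
  expect_equal(back$som$w, m$som$w)
  expect_equal(back$grossberg$z, m$grossberg$z)
  expect_equal(back$threshold, m$threshold)
  expect_identical(cpn_classify(back, coh), cpn_classify(m, coh))
})

test_that("training rejects single-class cohorts and bad schedules", {
  df <- as.data.frame(two_cluster_cohort(10))
  ctrl <- cohort(df[df$label == 0, ])
  expect_error(train_cpn(ctrl, c("mmse", "faq")), "both classes")
  expect_error(training_schedule(alpha0 = 0), "alpha0")
  expect_error(training_schedule(epochs = -1), "epochs")
  expect_error(training_schedule(gamma0 = 1.5), "gamma0")
})
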