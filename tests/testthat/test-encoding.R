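test_that("Poisson encoder: empty image, mean counts, linearity", {
  empty <- encode_poisson(matrix(0, 28, 28))
  expect_equal(length(empty$step), 0L)

  img <- matrix(0, 28, 28); img[5, 5] <- 255
  set.seed(1)
  counts <- replicate(200, length(encode_poisson(img, max_rate = 45,
                                                 duration_ms = 350)$step))
  # Poisson mean 45 * 0.35 = 15.75
  expect_lt(abs(mean(counts) - 15.75), 3 * sqrt(15.75 / 200))
  set.seed(2)
  counts2 <- replicate(200, length(encode_poisson(img, max_rate = 90,
                                                  duration_ms = 350)$step))
  expect_lt(abs(mean(counts2) / mean(counts) - 2), 0.2)
  expect_error(encode_poisson(img, max_rate = 3000, dt = 0.5), "aliasing")
  expect_error(encode_poisson(img - 300), "\\[0, 255\\]")
})

test_that("inter-spike intervals of a constant-rate pixel look exponential", {
  img <- matrix(0, 28, 28); img[1, 1] <- 255
  set.seed(42)
  steps <- integer(0)
  t_off <- 0
  while (length(steps) < 1e4) {
    r <- encode_poisson(img, max_rate = 60, duration_ms = 5000)
    steps <- c(steps, r$step + t_off)
    t_off <- t_off + r$n_steps
  }
  isi <- diff(steps) * 0.5
  # discrete geometric ISIs approximate the exponential; KS on the
  # continuous-ized intervals (jittered within a step)
  set.seed(43)
  isi_c <- isi - runif(length(isi), 0, 0.5)
  kt <- suppressWarnings(ks.test(isi_c, "pexp", rate = 60 / 1000))
  expect_gt(kt$p.value, 0.01)
})

test_that("Gaussian profile: mean rate, symmetry, flat limit", {
  gp <- gaussian_profile(400, center = 200.5, width = 40, mean_rate = 5)
  expect_equal(mean(gp$rates), 5, tolerance = 1e-12)
  expect_true(all(gp$rates >= 0))
  expect_lt(max(abs(gp$rates - rev(gp$rates))), 1e-9)
  flat <- gaussian_profile(400, width = 1e9, mean_rate = 5)
  expect_lt(max(abs(flat$rates - 5)), 1e-6)
  expect_error(gaussian_profile(400, width = 0), "width")
})

test_that("corpus generation is reproducible and dimensioned correctly", {
  c1 <- make_charset(c("CAT"), n_train_reps = 3, n_test_reps = 4,
                     rng_seed = 5)
  c2 <- make_charset(c("CAT"), n_train_reps = 3, n_test_reps = 4,
                     rng_seed = 5)
  expect_identical(c1$test, c2$test)
  expect_identical(c1$train, c2$train)
  expect_equal(length(c1$train), 3L)
  expect_equal(length(c1$train[[1]]), 3L)  # C, A, T
  for (img in c1$test$A) {
    expect_equal(dim(img), c(28L, 28L))
    expect_true(all(img >= 0 & img <= 255))
  }
  # distinct variants under default variability
  expect_false(identical(c1$test$A[[1]], c1$test$A[[2]]))
  # zero variability -> identical instances
  c0 <- make_charset("CAT", n_train_reps = 2, n_test_reps = 2,
                     variability = glyph_variability(scale = 0),
                     rng_seed = 1)
  expect_identical(c0$test$C[[1]], c0$test$C[[2]])
  expect_error(make_charset("cat1"), "A-Z")
  # repeated-character words are allowed but flagged
  cs <- make_charset(c("SEEN", "CAT"), n_train_reps = 1, n_test_reps = 1)
  expect_equal(cs$repeated_chars, "SEEN")
})

test_that("default variability preserves class identity >= 99%", {
  corpus <- make_charset(paste(LETTERS, collapse = ""), n_train_reps = 1,
                         n_test_reps = 12, rng_seed = 9)
  total <- 0; hits <- 0
  for (l in corpus$labels) for (img in corpus$test[[l]]) {
    total <- total + 1
    hits <- hits + (classify_nearest_template(img, corpus$templates) == l)
  }
  expect_gte(hits / total, 0.99)
})

test_that("presentation schedules follow the 350/300 ms protocol", {
  sched <- build_schedule("CAT", sim_params(dt = 0.5))
  expect_equal(nrow(sched), 4L)
  expect_equal(sched$label, c("C", "A", "T", NA))
  expect_equal(sched$n_steps, c(700L, 700L, 700L, 600L))
  expect_equal(sum(sched$n_steps), 2700L)
  single <- build_schedule("A", sim_params())
  expect_equal(sum(single$n_steps), 1300L)
  expect_true(all(sched$n_steps == round(sched$duration_ms / 0.5)))
  expect_error(build_schedule(""), "nonempty")
  expect_error(sim_params(dt = 0.3, presentation_ms = 350), "multiple")
})

test_that("corpus export writes portable graymaps plus a manifest", {
  corpus <- make_charset("AT", n_train_reps = 1, n_test_reps = 2,
                         rng_seed = 2)
  dir <- tempfile()
  manifest <- export_corpus(corpus, dir, max_per_label = 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 4L)
  pgm <- readLines(file.path(dir, manifest$file[1]))
  expect_equal(pgm[1], "P2")
  expect_equal(pgm[2], "28 28")
  vals <- scan(text = paste(pgm[-(1:3)], collapse = " "), quiet = TRUE)
  expect_equal(length(vals), 784L)
  unlink(dir, recursive = TRUE)
})
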