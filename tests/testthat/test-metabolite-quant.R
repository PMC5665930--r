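test_that("fit_calibration matches the least-squares oracle", {
  # noiseless line
  cv <- fit_calibration(data.frame(concentration_uM = c(1, 5, 10),
                                   area_ratio = c(2, 10, 20)))
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$residual_sd, 0)
  expect_equal(cv$llod, 0)
  expect_equal(cv$lloq, 0)

  # degenerate fits
  expect_error(fit_calibration(data.frame(concentration_uM = c(2, 2, 2),
                                          area_ratio = c(1, 2, 3))),
               "singular")
  expect_error(fit_calibration(data.frame(concentration_uM = 0:2,
                                          area_ratio = c(1, 1, 1))),
               "invalid assay")

  # hand-computed normal equations as the oracle
  x <- c(0, 1, 2, 4); y <- c(0.1, 2.1, 3.9, 8.1)
  beta <- solve(matrix(c(length(x), sum(x), sum(x), sum(x^2)), 2, 2),
                c(sum(y), sum(x * y)))
  cv <- fit_calibration(data.frame(concentration_uM = x, area_ratio = y))
  expect_equal(cv$intercept, beta[1], tolerance = 1e-12)
  expect_equal(cv$slope, beta[2], tolerance = 1e-12)
  resid <- y - beta[1] - beta[2] * x
  expect_equal(cv$residual_sd, sqrt(sum(resid^2) / 2), tolerance = 1e-12)
  expect_equal(cv$llod, 3.3 * cv$residual_sd / cv$slope)
  expect_equal(cv$lloq, 10 * cv$residual_sd / cv$slope)
})

make_tc <- function(ratios38, slope = 1, istd = 1000, individual = "S01",
                    timepoint = 3) {
  data.frame(individual = individual, timepoint_min = timepoint,
             replicate = seq_along(ratios38),
             area_sn38 = ratios38 * istd, area_sn38g = 0.5 * istd,
             area_istd = istd, stringsAsFactors = FALSE)
}

flat_curves <- function(slope = 1, intercept = 0) {
  cv <- list(slope = slope, intercept = intercept, llod = 0, lloq = 0)
  list(sn38 = cv, sn38g = cv)
}

test_that("quantify inverts the calibration line and summarises replicates", {
  tc <- rbind(make_tc(100, timepoint = 0), make_tc(100, timepoint = 3))
  q <- quantify(tc, flat_curves(slope = 2))
  expect_equal(q$conc_sn38, c(50, 50))   # ratio 100, slope 2 -> 50 uM

  # triplicate ratios 90/100/110 at slope 1: mean 100, sem = sd/sqrt(3)
  tc <- rbind(make_tc(c(90, 100, 110), timepoint = 0),
              make_tc(c(90, 100, 110), timepoint = 3))
  q <- quantify(tc, flat_curves())
  expect_equal(q$conc_sn38, c(100, 100))
  expect_equal(q$sem_sn38, rep(sd(c(90, 100, 110)) / sqrt(3), 2))

  # ratio below the intercept floors at 0 and is flagged below-LLOD
  tc <- make_tc(0.5, timepoint = 0)
  curves <- flat_curves()
  curves$sn38$intercept <- 1
  curves$sn38$llod <- 0.1
  q <- quantify(tc, curves)
  expect_equal(q$conc_sn38, 0)
  expect_true(q$below_llod_sn38)
})

test_that("quantify excludes zero-ISTD measurements and errors on empty cells", {
  tc <- rbind(make_tc(c(90, 100, 110), timepoint = 0),
              make_tc(c(90, 100, 110), timepoint = 3))
  tc$area_istd[4] <- 0
  expect_warning(q <- quantify(tc, flat_curves()), "internal-standard")
  expect_equal(q$n_replicates[q$timepoint_min == 3], 2L)
  tc$area_istd[4:6] <- 0
  expect_error(suppressWarnings(quantify(tc, flat_curves())),
               "lost all replicates")
})

test_that("percent_formation follows its definition and boundaries", {
  q <- data.frame(individual = c("A", "A", "B", "B"),
                  timepoint_min = c(0, 3, 0, 3),
                  conc_sn38 = c(0, 50, 0, 0))
  p <- percent_formation(q, substrate_initial = 100)
  expect_equal(unname(p[c("A", "B")]), c(50, 0))
  expect_error(percent_formation(q[q$individual != "B" | q$timepoint_min == 0, ],
                                 100), "missing final timepoint")
  expect_error(percent_formation(q, 0), "substrate_initial")
})

test_that("zero-noise end-to-end run reproduces the planted maximum 77.11%", {
  spec <- cohort_spec(n_low = 0, n_high = 1, high_range = c(77.11, 77.11),
                      noise_cv = 0)
  sim <- simulate_turnover(spec)
  q <- quantify(sim$table, sim$truth$curves)
  p <- percent_formation(q, sim$truth$substrate0_uM)
  expect_equal(unname(p), 77.11, tolerance = 1e-9)
})

test_that("round trip: noiseless simulation + true curves gives exact concentrations", {
  sim <- simulate_turnover(cohort_spec(noise_cv = 0))
  q <- quantify(sim$table, sim$truth$curves)
  p <- percent_formation(q, sim$truth$substrate0_uM)
  truth <- sim$truth$labels
  expect_equal(unname(p[truth$individual]), truth$percent_formation,
               tolerance = 1e-9)
})

test_that("classify_metabotype splits at the largest gap", {
  p <- setNames(c(0.5, 1, 2, 40, 60), paste0("S", 1:5))
  cl <- classify_metabotype(p)
  expect_equal(sum(cl$assignments$metabotype == "low"), 3L)
  expect_equal(sum(cl$assignments$metabotype == "high"), 2L)
  expect_equal(cl$split_gap, 38)
  expect_true(cl$threshold > 2 && cl$threshold < 40)

  # below the min-gap guard the cohort is unimodal: all low
  cl <- classify_metabotype(setNames(1:4, paste0("S", 1:4)), min_gap = 10)
  expect_true(all(cl$assignments$metabotype == "low"))
  expect_error(classify_metabotype(setNames(1, "S1")), "at least 2")
})

test_that("classification invariants hold on random cohorts", {
  set.seed(42)
  for (i in 1:50) {
    p <- setNames(runif(15, 0, 80), sprintf("S%02d", 1:15))
    cl <- classify_metabotype(p)
    a <- cl$assignments
    if (any(a$metabotype == "high")) {
      expect_gt(min(a$percent_formation[a$metabotype == "high"]),
                max(a$percent_formation[a$metabotype == "low"]))
    }
  }
})

test_that("raising an individual's analyte signal never demotes them to low", {
  sim <- simulate_turnover(cohort_spec(seed = 4))
  q <- quantify(sim$table, sim$truth$curves)
  p <- percent_formation(q, 100)
  base <- classify_metabotype(p)$assignments
  hi_id <- base$individual[base$metabotype == "high"][1]
  p2 <- p
  p2[hi_id] <- p2[hi_id] * 1.2
  again <- classify_metabotype(p2)$assignments
  expect_equal(again$metabotype[again$individual == hi_id], "high")
})

test_that("correlate_assays matches the t-transform oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_assays(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_assays(x, -x)$r, -1)
  res <- correlate_assays(x, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  t_hand <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(res$p, 2 * pt(-t_hand, df = 2), tolerance = 1e-12)
  expect_error(correlate_assays(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate_assays(1:2, 1:2), "n >= 3")
})
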