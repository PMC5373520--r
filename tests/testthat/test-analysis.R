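test_that("peak amplitude pools units before peaking", {
  tr <- tic_trial_fixture(seed = 3)
  flat <- tr
  flat$traces[] <- 7
  expect_equal(peak_amplitude(flat, "M1"), 7)
  expect_error(peak_amplitude(tr, "Cortex"), "unknown area")

  # pooled putamen equals the mean of StrD1 and StrD2 unit traces, peaked
  str_idx <- grep("^StrD[12]_", colnames(tr$traces))
  expect_equal(peak_amplitude(tr, "DorsalPutamen"),
               max(rowMeans(tr$traces[, str_idx])))
  # invariant to unit permutation within the area
  perm <- tr
  perm$traces[, str_idx] <- perm$traces[, sample(str_idx)]
  expect_equal(peak_amplitude(perm, "DorsalPutamen"),
               peak_amplitude(tr, "DorsalPutamen"))
})

test_that("onset delay recovers constructed shifts with the stated sign", {
  t <- seq(0, 2, by = 0.001)
  x <- dnorm(t, 1, 0.1) + 0.02 * sin(40 * t)
  expect_equal(onset_delay(x, x, dt = 0.001), 0)

  # `other` shifted later by 126 steps: the reference leads by 0.126 s
  y <- c(rep(x[1], 126), x[1:(length(x) - 126)])
  expect_equal(onset_delay(x, y, dt = 0.001), -0.126)
  # and symmetrically, the earlier trace leads
  expect_equal(onset_delay(y, x, dt = 0.001), 0.126)

  # antisymmetry and offset invariance
  set.seed(8)
  b <- cumsum(rnorm(500)) / 10 + dnorm(seq(0, 2, length.out = 500), 1, 0.2) * 30
  c2 <- c(rep(b[1], 40), b[1:460])
  expect_equal(onset_delay(b, c2, 0.001), -onset_delay(c2, b, 0.001))
  expect_equal(onset_delay(b, c2, 0.001), onset_delay(b + 100, c2 - 50, 0.001))

  expect_error(onset_delay(rep(1, 100), x[1:100], 0.001), "flat")
})

test_that("an inverted response is located by the same correlogram peak", {
  # an area responding with a firing DECREASE at a lead is assigned that
  # lead, as for an increasing area
  t <- seq(0, 2, by = 0.001)
  m1 <- dnorm(t, 1.2, 0.12) * 50
  dip <- 100 - dnorm(t, 1.08, 0.12) * 48
  expect_equal(onset_delay(m1, dip, dt = 0.001), 0.12, tolerance = 0.2)
  expect_gt(onset_delay(m1, dip, dt = 0.001), 0.08)
})

test_that("latency table computes per-subject delays against M1", {
  lt <- latency_table(small_cohort())
  expect_true(all(lt$area %in% areas()))
  expect_true(all(lt$delay_s[lt$area == "M1"] == 0))
  expect_true(all(abs(lt$delay_s) <= 2))
})

test_that("two-way ANOVA matches brute-force sums of squares on a small table", {
  set.seed(21)
  tbl <- tidyr::expand_grid(subject = 1:3,
                            area = c("A", "B"), state = c("TIC", "NO-TIC"))
  mu <- c(A.TIC = 10, `A.NO-TIC` = 10, B.TIC = 30, `B.NO-TIC` = 12)
  tbl$peak <- mu[paste(tbl$area, tbl$state, sep = ".")] + rnorm(12, 0, 2)

  an <- area_state_anova(tbl, alpha = 0.05)
  got <- tidy(an)

  # independent computation from first principles
  y <- tbl$peak
  g <- interaction(tbl$area, tbl$state)
  ss_total <- sum((y - mean(y))^2)
  m_area <- tapply(y, tbl$area, mean); m_state <- tapply(y, tbl$state, mean)
  m_cell <- tapply(y, g, mean)
  ss_area <- sum(3 * 2 * (m_area - mean(y))^2)
  ss_state <- sum(3 * 2 * (m_state - mean(y))^2)
  ss_cells <- sum(3 * (m_cell - mean(y))^2)
  ss_int <- ss_cells - ss_area - ss_state
  ss_res <- ss_total - ss_cells
  f_int <- (ss_int / 1) / (ss_res / 8)

  expect_equal(got$sumsq[got$term == "area:state"], ss_int)
  expect_equal(got$statistic[got$term == "area:state"], f_int)
  # the differing area is flagged, the null area is not
  ph <- an$posthoc
  expect_true(ph$significant[ph$area == "B"])
  expect_false(ph$significant[ph$area == "A"])
})

test_that("null peak tables produce no significant interaction", {
  set.seed(4)
  tbl <- tidyr::expand_grid(subject = 1:20,
                            area = areas(), state = c("TIC", "NO-TIC"))
  tbl$peak <- rnorm(nrow(tbl), 50, 5)
  an <- area_state_anova(tbl)
  expect_gt(glance(an)$p_value, 0.001)
  expect_true(all(!an$posthoc$significant))
})

test_that("latency ANOVA separates two synthetic delay clusters", {
  set.seed(12)
  lead <- c("DorsalPutamen", "GPe", "GPi")
  tbl <- tidyr::expand_grid(subject = 1:40, area = areas())
  tbl$delay_s <- ifelse(tbl$area %in% lead, 0.12, 0) + rnorm(nrow(tbl), 0, 0.01)
  tbl$delay_s[tbl$area == "M1"] <- 0
  an <- latency_anova(tbl)
  expect_lt(glance(an)$p_value, 0.001)
  ph <- an$posthoc
  expect_true(all(ph$significant[ph$area %in% lead]))
  expect_true(all(!ph$significant[ph$area %in% c("STN", "Th", "CbllCx")]))

  # all-equal delays: nothing separates
  tbl$delay_s <- 0.05 + rnorm(nrow(tbl), 0, 0.01)
  expect_gt(glance(latency_anova(tbl))$p_value, 0.001)
})

test_that("dose-response ANOVA detects a level effect only when present", {
  set.seed(2)
  flat <- tidyr::expand_grid(subject = 1:10, da_height = seq(0, 100, 25))
  flat$n_tics <- rpois(nrow(flat), 5)
  expect_gt(glance(dose_response_anova(flat))$p_value, 0.001)

  rising <- flat
  rising$n_tics <- rpois(nrow(rising), 1 + rising$da_height / 10)
  expect_lt(glance(dose_response_anova(rising))$p_value, 0.001)
})
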