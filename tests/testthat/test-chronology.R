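test_that("clock calibration fits the two-point line exactly", {
  cl <- calibrate_clock(tibble::tibble(x = c(0, 1), age_gy = c(3.8, 0)))
  expect_equal(cl$slope, -3.8)
  expect_equal(cl$intercept, 3.8)
  expect_equal(cl$r_squared, 1)
  expect_error(calibrate_clock(tibble::tibble(x = 0.5, age_gy = 2)), "2 distinct")
  expect_error(calibrate_clock(tibble::tibble(x = c(0.5, 0.5), age_gy = c(1, 2))),
               "2 distinct")
})

test_that("clock recovers a known line from noisy calibration points", {
  set.seed(9)
  x <- runif(20)
  pts <- tibble::tibble(x = x, age_gy = 3.8 - 3.8 * x + rnorm(20, 0, 0.1))
  cl <- calibrate_clock(pts)
  se <- tidy(cl)$std.error[2]
  expect_lt(abs(cl$slope - (-3.8)), 3 * se)
  expect_gt(cl$r_squared, 0.9)
})

test_that("collinear calibrations reproduce their own ages exactly", {
  pts <- tibble::tibble(x = c(0, 0.25, 0.5, 1), age_gy = 4 - 4 * c(0, 0.25, 0.5, 1))
  cl <- calibrate_clock(pts)
  expect_equal(cl$r_squared, 1)
  tl <- apply_clock(cl, tibble::tibble(unit = paste0("u", 1:4), x = pts$x))
  expect_equal(tl$age_gy, pts$age_gy, tolerance = 1e-12)
  expect_true(all(tl$flags == ""))
})

test_that("clock application clamps and flags out-of-range predictions", {
  cl <- calibrate_clock(tibble::tibble(x = c(0, 1), age_gy = c(3.8, 0)))
  tl <- apply_clock(cl, tibble::tibble(unit = "mid", x = 0.5))
  expect_equal(tl$age_gy, 1.9)
  extra <- apply_clock(cl, tibble::tibble(unit = "beyond", x = 1.5))
  expect_match(extra$flags, "extrapolated")
  expect_match(extra$flags, "clamped")
  expect_equal(extra$age_gy, 0)   # negative prediction clamped to zero
  old <- apply_clock(calibrate_clock(tibble::tibble(x = c(0, 1), age_gy = c(5, 0))),
                     tibble::tibble(unit = "deep", x = 0))
  expect_equal(old$age_gy, 4.2)   # ceiling
  expect_match(old$flags, "clamped")
})

test_that("interaction anchoring assigns the oldest partner's age", {
  ages <- tibble::tibble(unit = c("d.104.1.1", "b.51.1.1", "c.51.1.1"),
                         age_gy = c(3.7, 3.3, 3.0))
  map <- tibble::tibble(domain_id = c("d.104.1.1", "b.51.1.1", "c.51.1.1"),
                        substructure = c("acceptor", "d_arm", "anticodon_arm"),
                        evidence = "literature")
  tl <- anchor_substructures(ages, map)
  expect_equal(tl$age_gy[match(c("acceptor", "d_arm", "anticodon_arm"), tl$unit)],
               c(3.7, 3.3, 3.0))
  expect_true(all(tl$provenance == "interaction-anchor"))
  empty <- anchor_substructures(ages, map[0, ])
  expect_equal(nrow(empty), 0L)
  expect_error(anchor_substructures(ages,
                                    tibble::tibble(domain_id = "zzz",
                                                   substructure = "acceptor")),
               "unknown domain")
})

test_that("anchoring is monotone under added older partners", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    ages <- tibble::tibble(unit = paste0("d", 1:n), age_gy = runif(n, 1, 4))
    map <- tibble::tibble(domain_id = sample(ages$unit, n, TRUE),
                          substructure = sample(c("acceptor", "d_arm"), n, TRUE))
    base <- anchor_substructures(ages, map)
    older <- dplyr::bind_rows(ages, tibble::tibble(unit = "dX", age_gy = 4.1))
    map2 <- dplyr::bind_rows(map, tibble::tibble(domain_id = "dX",
                                                 substructure = "acceptor"))
    more <- anchor_substructures(older, map2)
    a0 <- base$age_gy[base$unit == "acceptor"]
    a1 <- more$age_gy[more$unit == "acceptor"]
    if (length(a0) == 1) expect_gte(a1, a0)
  }
})

test_that("interaction ages take the youngest component", {
  ages <- tibble::tibble(unit = "d1", age_gy = 3.5)
  subs <- tibble::tibble(unit = "acceptor", age_gy = 3.0)
  map <- tibble::tibble(domain_id = "d1", substructure = "acceptor")
  ia <- interaction_ages(ages, map, subs)
  expect_equal(ia$age_gy, 3.0)
  expect_equal(interaction_ages(ages, map)$age_gy, 3.5)
})

test_that("order conflicts between anchored and tree ages raise flags", {
  anchored <- tibble::tibble(unit = c("acceptor", "d_arm"), kind = "substructure",
                             age_gy = c(3.7, 3.3),
                             provenance = "interaction-anchor", flags = "")
  # tree says d_arm is MORE basal than acceptor: a deliberate contradiction
  rel <- tibble::tibble(taxon = c("acceptor", "d_arm"), relative_age = c(0.2, 0.9))
  chk <- check_timeline_consistency(anchored, rel)
  expect_false(any(chk$consistent))
  expect_match(chk$flags[1], "order-conflict")
  # concordant orders stay clean
  rel_ok <- tibble::tibble(taxon = c("acceptor", "d_arm"), relative_age = c(0.9, 0.2))
  chk2 <- check_timeline_consistency(anchored, rel_ok)
  expect_true(all(chk2$consistent))
})

test_that("timeline TSV/JSON writers emit provenance columns", {
  tl <- tibble::tibble(unit = "acceptor", kind = "substructure", age_gy = 3.7,
                       provenance = "interaction-anchor", flags = "")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_timeline(tl, tmp, json = TRUE)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(back$provenance, "interaction-anchor")
  expect_true(file.exists(sub("\\.tsv$", ".json", tmp)))
})
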