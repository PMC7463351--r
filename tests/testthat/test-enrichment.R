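test_that("mean expression matches a row-mean oracle and flags zero genes", {
  set.seed(50)
  norm <- matrix(runif(60, 0, 100), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("S", 1:6)))
  norm["g3", ] <- 7
  norm["g9", ] <- 0
  m <- mean_expression(norm, paste0("g", 1:10))
  for (g in rownames(norm))
    expect_equal(m[[g]], sum(norm[g, ]) / ncol(norm), tolerance = 1e-12)
  expect_equal(m[["g3"]], 7)
  expect_identical(attr(m, "zero_genes"), "g9")
  expect_error(mean_expression(norm, c("g1", "nope")), "nope")
})

test_that("equal-width bins reproduce the study's printed edges", {
  set.seed(51)
  means <- c(0.02, 7600, runif(177, 0.05, 7000))
  names(means) <- sprintf("c%03d", seq_along(means))
  scheme <- compute_bins(means, 10L)
  width <- (7600 - 0.02) / 10
  expect_equal(scheme$edges[2], 0.02 + width, tolerance = 1e-9)
  expect_lt(abs(scheme$edges[2] - 760.01), 0.5)
  expect_lt(abs(scheme$edges[3] - 1520), 0.5)
  expect_equal(diff(scheme$edges), rep(width, 10), tolerance = 1e-9)
})

test_that("bin assignment is exhaustive and matches a brute-force loop", {
  x <- setNames(seq(0, 10, length.out = 30), sprintf("g%02d", 1:30))
  scheme <- compute_bins(x, 10L)
  expect_equal(scheme$edges, 0:10)
  # brute force: right-open intervals, last closed
  brute <- vapply(x, function(v) {
    for (k in 1:10)
      if ((v >= scheme$edges[k] && v < scheme$edges[k + 1]) ||
          (k == 10 && v == scheme$edges[11])) return(k)
    NA_integer_
  }, integer(1))
  expect_identical(unname(scheme$assignment), unname(brute))
  expect_equal(sum(scheme$candidate_counts), length(x))
  expect_equal(sum(scheme$candidate_props), 1)
  expect_error(compute_bins(setNames(rep(1, 20), paste0("g", 1:20))),
               "distinct")
})

make_scheme <- function(occupancy, lo = 0.02, hi = 7600) {
  # construct candidate means hitting a prescribed per-bin occupancy
  edges <- seq(lo, hi, length.out = length(occupancy) + 1L)
  means <- unlist(lapply(seq_along(occupancy), function(k) {
    if (occupancy[k] == 0) return(numeric(0))
    seq(edges[k], edges[k + 1] - 1e-6, length.out = occupancy[k] + 2)[
      seq_len(occupancy[k]) + 1]
  }))
  names(means) <- sprintf("c%03d", seq_along(means))
  compute_bins(means, length(occupancy))
}

test_that("sparse high-expression bins are dropped, 179 genes become 175", {
  # study-like occupancy: 156 + 15 in the first two bins, a sparse tail,
  # and 4 genes in two >3000-count bins with <= 2 genes each
  scheme <- make_scheme(c(156, 15, 3, 1, 0, 0, 0, 2, 0, 2))
  expect_equal(sum(scheme$candidate_counts), 179)
  filt <- filter_bins(scheme)
  lower <- scheme$edges[1:10]
  expect_identical(filt$retained, !(lower > 3000 & scheme$candidate_counts < 3))
  expect_equal(sum(filt$candidate_counts), 175)
  expect_length(filt$dropped_genes, 4L)
  expect_equal(sum(filt$candidate_props), 1)
})

test_that("the bin filter leaves compliant schemes unchanged", {
  scheme <- make_scheme(c(100, 50, 20, 10, 5, 5, 4, 3, 3, 3))
  filt <- filter_bins(scheme)
  expect_identical(filt$candidate_counts, scheme$candidate_counts)
  expect_identical(filt$assignment, scheme$assignment)

  # low-expression sparse bins are never dropped
  low <- make_scheme(c(1, 2, 100, 50, 20, 10, 5, 4, 3, 3), lo = 0, hi = 100)
  expect_identical(filter_bins(low)$candidate_counts, low$candidate_counts)
})

test_that("background assembly is a set union", {
  u <- gene_set("u", sprintf("u%03d", 1:100))
  d <- gene_set("d", sprintf("d%02d", 1:10))
  cand <- gene_set("c", sprintf("c%02d", 1:5))
  expect_length(suppressMessages(build_background(u, d, cand))$gene_ids, 115L)
  d_sub <- gene_set("d", u$gene_ids[1:10])
  expect_length(suppressMessages(build_background(u, d_sub, cand))$gene_ids, 105L)
  set.seed(52)
  for (i in 1:10) {
    a <- sample(letters, 10); b <- sample(letters, 5); c3 <- sample(letters, 3)
    got <- suppressMessages(build_background(a, b, c3))$gene_ids
    expect_setequal(got, unique(c(a, b, c3)))
  }
})

test_that("matched subsampling hits the frozen allocation examples", {
  # proportional availability: everything is used
  scheme <- make_scheme(c(60, 30, 8, 2, 1, 1, 1, 1, 2, 4))
  props <- scheme$candidate_props
  bg <- unlist(lapply(1:10, function(k) {
    n_avail <- scheme$candidate_counts[k] * 3L
    if (n_avail == 0) return(numeric(0))
    mid <- (scheme$edges[k] + scheme$edges[k + 1]) / 2
    rep(mid, n_avail)
  }))
  names(bg) <- sprintf("b%04d", seq_along(bg))
  mb <- match_background(bg, scheme, seed = 9)
  expect_equal(mb$total_n, 3L * sum(scheme$candidate_counts))
  expect_identical(mb$per_bin_counts, scheme$candidate_counts * 3L)
  expect_identical(unname(mb$availability), unname(mb$per_bin_counts))

  # two-bin worked example: props (0.9, 0.1), availability (900, 5)
  two <- compute_bins(setNames(c(seq(0, 0.999, length.out = 90),
                                 seq(1.001, 2, length.out = 10)),
                               sprintf("c%03d", 1:100)), 2L)
  expect_equal(two$candidate_props, c(0.9, 0.1))
  bg2 <- setNames(c(runif(900, 0, 0.999), runif(5, 1.001, 2)),
                  sprintf("b%03d", 1:905))
  mb2 <- match_background(bg2, two, seed = 1)
  expect_equal(mb2$total_n, 50L)
  expect_identical(mb2$per_bin_counts, c(45L, 5L))
})

test_that("out-of-range background genes are excluded before matching", {
  scheme <- compute_bins(setNames(seq(10, 110, length.out = 20),
                                  sprintf("c%02d", 1:20)), 10L)
  bg <- setNames(c(runif(200, 10, 110), runif(50, 0, 9), runif(50, 120, 500)),
                 sprintf("b%03d", 1:300))
  mb <- match_background(bg, scheme, seed = 4)
  expect_equal(mb$n_out_of_range, 100L)
  expect_true(all(mb$gene_ids %in% names(bg)[1:200]))
})

test_that("matched proportions converge to candidate proportions", {
  set.seed(53)
  scheme <- make_scheme(c(120, 30, 15, 8, 4, 3, 3, 3, 2, 2) * 1L,
                        lo = 0, hi = 100)
  bg <- setNames(runif(20000, 0, 100), sprintf("b%05d", 1:20000))
  mb <- match_background(bg, scheme, seed = 11)
  got_props <- mb$per_bin_counts / mb$total_n
  expect_lte(max(abs(got_props - scheme$candidate_props)), 1 / mb$total_n)
})

test_that("match verification behaves like the study's check", {
  ident <- verify_match(c(50, 30, 20), c(50, 30, 20))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)
  expect_true(ident$matched)

  # hand-computed 2-bin Yates example against the textbook formula
  res <- verify_match(c(40, 10), c(35, 15))
  obs <- cbind(c(40, 10), c(35, 15))
  expect_equal(res$chi2, oracle_yates(obs), tolerance = 1e-12)

  expect_warning(v <- verify_match(c(10, 0, 10), c(12, 0, 8)), "empty bin")
  expect_error(verify_match(c(0, 0), c(0, 0)), "non-empty")
})

test_that("matched output passes the chi-square match check across seeds", {
  sim <- simulate_experiment(sim_config(n_background_genes = 3000,
                                        n_candidate_genes = 150, seed = 54))
  sf <- estimate_size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  cand_means <- mean_expression(norm, intersect(sim$candidates$gene_ids,
                                                rownames(norm)))
  cand_means <- cand_means[cand_means > 0]
  scheme <- filter_bins(compute_bins(cand_means, 10L))
  bg_means <- mean_expression(norm, sim$background$gene_ids)
  active <- scheme$candidate_counts > 0
  for (s in 1:20) {
    mb <- match_background(bg_means, scheme, seed = s)
    vm <- verify_match(scheme$candidate_counts[active],
                       mb$per_bin_counts[active])
    expect_gt(vm$p, 0.99)
  }
})

test_that("the Yates statistic reproduces the study's enrichment table", {
  hl <- yates_chi2(29, 813, 175, 11656)
  expect_equal(hl$chi2, 17.94, tolerance = 0.01 / 17.94)
  expect_equal(hl$p, 2.3e-5, tolerance = 0.03)
  hm <- yates_chi2(18, 669, 175, 11656)
  expect_equal(hm$chi2, 4.84, tolerance = 0.01 / 4.84)
  expect_equal(hm$p, 0.028, tolerance = 0.02)
  ml <- yates_chi2(18, 703, 175, 11656)
  expect_equal(ml$chi2, 4.00, tolerance = 0.01 / 4.00)
  expect_equal(ml$p, 0.046, tolerance = 0.02)
})

test_that("proportional tables score zero and degenerate tables error", {
  prop <- yates_chi2(10, 100, 10, 100)
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  expect_error(yates_chi2(0, 0, 5, 10), "margin")
  expect_error(yates_chi2(-1, 10, 5, 10), "non-negative")
})

test_that("the Yates statistic is symmetric and matches oracles", {
  set.seed(55)
  for (i in 1:200) {
    cells <- rpois(4, 50) + 1L
    ours <- yates_chi2(cells[1], cells[2], cells[3], cells[4])
    obs <- matrix(cells, 2, 2, byrow = TRUE)
    expect_equal(ours$chi2, oracle_yates(obs), tolerance = 1e-12)
    # independent reference implementation
    ref <- suppressWarnings(chisq.test(obs, correct = TRUE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # row and column swaps leave the statistic unchanged
    expect_equal(yates_chi2(cells[3], cells[4], cells[1], cells[2])$chi2,
                 ours$chi2, tolerance = 1e-12)
    expect_equal(yates_chi2(cells[2], cells[1], cells[4], cells[3])$chi2,
                 ours$chi2, tolerance = 1e-12)
  }
})

test_that("the nested table option uses the conventional partition", {
  res <- yates_chi2(29, 813, 175, 11656, nested = TRUE)
  ref <- suppressWarnings(chisq.test(matrix(
    c(29, 175 - 29, 813 - 29, 11656 - 175 - 813 + 29), 2, 2, byrow = TRUE)))
  expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_error(yates_chi2(20, 10, 5, 100, nested = TRUE), "negative cells")
})

test_that("enrichment calls require both significance and direction", {
  paper <- list(
    "highland-lowland" = list(candidate_de = 29, de_total = 813,
                              candidate_bg = 175, bg_total = 11656),
    "highland-midland" = list(candidate_de = 18, de_total = 669,
                              candidate_bg = 175, bg_total = 11656),
    "midland-lowland" = list(candidate_de = 18, de_total = 703,
                             candidate_bg = 175, bg_total = 11656))
  rep <- enrichment_report(paper)
  expect_identical(rep$enriched, rep("Yes", 3))
  expect_equal(rep$chi2, c(17.94, 4.84, 4.00), tolerance = 0.002)

  # significant depletion is not enrichment
  depl <- enrichment_report(list(x = list(candidate_de = 2, de_total = 800,
                                          candidate_bg = 175, bg_total = 11656)))
  expect_identical(depl$enriched, "No")

  set.seed(56)
  for (i in 1:50) {
    r <- list(candidate_de = rpois(1, 20) + 1, de_total = rpois(1, 500) + 50,
              candidate_bg = rpois(1, 150) + 1, bg_total = rpois(1, 8000) + 500)
    rep1 <- enrichment_report(list(x = r))
    manual <- with(r, candidate_de / de_total > candidate_bg / bg_total)
    p <- yates_chi2(r$candidate_de, r$de_total, r$candidate_bg, r$bg_total)$p
    expect_identical(rep1$enriched == "Yes", manual && p < 0.05)
  }
})
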