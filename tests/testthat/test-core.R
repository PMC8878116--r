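test_that("the worked 4x5 table yields core {A, C} with a 72.5% share", {
  tab <- worked_core_table()
  core <- select_core(tab)
  expect_equal(core_otu_ids(core), c("A", "C"))
  ev <- core$evidence
  # B fails occupancy (3/4), D fails the abundant criterion, E sits at
  # exactly 1% mean relative abundance (strict > excludes it)
  expect_equal(ev$occupancy_fraction[ev$otu_id == "B"], 0.75)
  expect_equal(ev$abundant_fraction[ev$otu_id == "D"], 0)
  expect_equal(ev$mean_relative_abundance[ev$otu_id == "E"], 0.01)
  expect_false(any(ev$is_core[ev$otu_id %in% c("B", "D", "E")]))
  expect_equal(core$summary$core_share_mean, 0.725)
  expect_equal(unname(core$summary$per_sample_core_share),
               c(0.65, 0.60, 0.95, 0.70))
})

test_that("degenerate tables behave per contract", {
  one <- otu_table(matrix(c(100, 100), 2, 1,
                          dimnames = list(c("s1", "s2"), "X")))
  core <- select_core(one)
  expect_equal(core_otu_ids(core), "X")
  expect_equal(core$summary$core_share_mean, 1)
  # occupancy_min = 1 excludes any OTU with a zero
  tab <- worked_core_table()
  core2 <- select_core(tab, core_criteria(occupancy_min = 1))
  expect_false("B" %in% core_otu_ids(core2))
  # empty core is a result, not an error
  core3 <- select_core(tab, core_criteria(mean_ra_min = 0.999))
  expect_equal(core3$summary$n_core, 0)
  expect_equal(core3$summary$core_share_mean, 0)
})

test_that("abundant set is the smallest prefix reaching the threshold", {
  x <- c(A = 50, B = 30, C = 15, D = 4, E = 1)
  expect_equal(abundant_otus(x, 0.8), c("A", "B"))  # hits 0.8 exactly at B
  expect_equal(abundant_otus(c(X = 7)), "X")
  expect_equal(length(abundant_otus(rep(c(u = 10), 5) |>
                                      setNames(letters[1:5]), 0.8)), 4)
  # ties at the boundary resolve lexicographically
  y <- c(b = 10, a = 10, c = 1)
  expect_equal(abundant_otus(y, 0.4), "a")
})

test_that("occupancy counts detection (count >= 1) per sample", {
  m <- rbind(c(1, 0, 3), c(2, 0, 0), c(5, 0, 1), c(9, 0, 2))
  colnames(m) <- c("x", "y", "z")
  rownames(m) <- paste0("s", 1:4)
  occ <- occupancy(otu_table(m, require_positive_samples = FALSE))
  expect_equal(unname(occ), c(1, 0, 0.75))
})

test_that("cumulative rank curve aggregates per-sample sorted shares", {
  one <- otu_table(matrix(c(80, 20), 1, 2, dimnames = list("s1", NULL)))
  expect_equal(cumulative_rank_curve(one)$mean, c(0.8, 1.0))
  uni <- otu_table(matrix(rep(5, 10), 1, 10, dimnames = list("s1", NULL)))
  expect_equal(cumulative_rank_curve(uni)$mean, (1:10) / 10)
  two <- otu_table(rbind(s1 = c(80, 20), s2 = c(60, 40)))
  cc <- cumulative_rank_curve(two)
  expect_equal(cc$mean[1], 0.7)
  expect_equal(cc$sd[1], sd(c(0.8, 0.6)))
})

test_that("occupancy bins partition the OTUs and their abundance", {
  tab <- worked_core_table()
  bins <- occupancy_abundance_bins(tab)
  expect_equal(sum(bins$n_otus), n_otus(tab))
  expect_equal(sum(bins$relative_abundance), 1, tolerance = 1e-12)
  # everything detected everywhere lands in the last bin
  full <- otu_table(matrix(1:6, 2, 3))
  bf <- occupancy_abundance_bins(full)
  expect_equal(bf$n_otus[20], 3)
  expect_equal(bf$relative_abundance[20], 1)
  # constructed occupancies 0.5 and 0.9 hit the (45,50] and (85,90] bins
  m <- matrix(0, 20, 3, dimnames = list(sprintf("s%02d", 1:20),
                                        c("h", "l", "f")))
  m[1:18, "h"] <- 5
  m[1:10, "l"] <- 5
  m[19:20, "f"] <- 1  # filler keeps the last rows non-empty
  bx <- occupancy_abundance_bins(otu_table(m))
  expect_equal(bx$n_otus[bx$bin_low == 0.45], 1)
  expect_equal(bx$n_otus[bx$bin_low == 0.85], 1)
  expect_error(occupancy_abundance_bins(tab, bin_width = 0.3), "divide")
})

test_that("selection agrees with the brute-force oracle on random tables", {
  for (seed in 1:40) {
    tab <- random_table(sample(2:8, 1), sample(5:30, 1), seed = 400 + seed)
    expect_equal(core_otu_ids(select_core(tab)), brute_force_core(tab),
                 info = paste("seed", seed))
  }
})

test_that("relaxing any single criterion never shrinks the core", {
  base <- core_criteria()
  for (seed in 1:10) {
    tab <- random_table(6, 20, seed = 500 + seed)
    core0 <- core_otu_ids(select_core(tab, base))
    relaxed <- list(core_criteria(mean_ra_min = 0.001),
                    core_criteria(occupancy_min = 0.4),
                    core_criteria(abundant_sample_frac_min = 0.2))
    for (cr in relaxed)
      expect_true(all(core0 %in% core_otu_ids(select_core(tab, cr))))
  }
})

test_that("summary share is internally consistent with the evidence", {
  tab <- random_table(6, 25, seed = 77)
  core <- select_core(tab, core_criteria(mean_ra_min = 0.02,
                                         occupancy_min = 0.5,
                                         abundant_sample_frac_min = 0.3))
  ids <- core_otu_ids(core)
  if (length(ids)) {
    ra <- relative_abundance(tab)
    expect_equal(core$summary$core_share_mean,
                 mean(rowSums(ra[, ids, drop = FALSE])), tolerance = 1e-12)
  }
})

test_that("strict every-sample reading is more conservative", {
  tab <- worked_core_table()
  strict <- select_core(tab, strict_every_sample = TRUE)
  expect_true(all(core_otu_ids(strict) %in% core_otu_ids(select_core(tab))))
  # B drops to 0 in sample s3, so a strict 1% floor excludes it everywhere
  expect_false("B" %in% core_otu_ids(strict))
})

test_that("per-group cores are computed independently", {
  tab <- worked_core_table()
  m2 <- tab$counts
  rownames(m2) <- paste0("t", 1:4)
  both <- otu_table(rbind(tab$counts, m2))
  md <- data.frame(sample_id = sample_ids(both),
                   group = rep(c("P1", "P2"), each = 4))
  cores <- per_group_core(both, md)
  expect_equal(core_otu_ids(cores$P1), c("A", "C"))
  expect_equal(core_otu_ids(cores$P2), c("A", "C"))
  # a group-specific dominant OTU enters only that group's core
  m3 <- both$counts
  m3[5:8, "D"] <- 200
  cores3 <- per_group_core(otu_table(m3), md)
  expect_false("D" %in% core_otu_ids(cores3$P1))
  expect_true("D" %in% core_otu_ids(cores3$P2))
  expect_warning(per_group_core(both, transform(
    md, group = c(rep("P1", 7), "solo"))), "solo")
})

test_that("the national core need not nest inside provincial cores", {
  # X is ubiquitous nationally (11/12 samples) but misses occupancy in the
  # second, smaller province (3/4)
  m <- matrix(0, 12, 3, dimnames = list(sprintf("s%02d", 1:12),
                                        c("X", "Y", "Z")))
  m[, "X"] <- 80; m[, "Y"] <- 15; m[, "Z"] <- 5
  m[12, ] <- c(0, 80, 20)
  tab <- otu_table(m)
  md <- data.frame(sample_id = sample_ids(tab),
                   group = rep(c("P1", "P2"), c(8, 4)))
  national <- core_otu_ids(select_core(tab))
  provincial <- per_group_core(tab, md)
  expect_true("X" %in% national)
  expect_false("X" %in% core_otu_ids(provincial$P2))
})
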