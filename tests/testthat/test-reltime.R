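test_that("clock-like trees yield exact node depths and calibrated ages", {
  ct <- simulate_clock_tree(8, rate_sigma = 0, seed = 2)
  tre <- attach_outgroup(ct$time_tree)
  tips <- ct$time_tree$tip.label
  cal <- tibble::tibble(taxon_a = tips[1], taxon_b = tips[8], age = 55.54)
  res <- reltime_date(tre, "OUT", cal)
  # map nodes between the (renumbered) ingroup and the original tree
  key_true <- clade_keys(ct$time_tree)
  key_est <- clade_keys(res$tree)
  nt <- ape::Ntip(ct$time_tree)
  true_int <- ct$true_heights[(nt + 1):(nt + ct$time_tree$Nnode)]
  est_int <- res$relative_heights[(nt + 1):(nt + res$tree$Nnode)]
  est_mapped <- est_int[match(key_true, key_est)]
  expect_equal(est_mapped, true_int, tolerance = 1e-10)
  # calibrated node sits exactly at its age; tips at zero
  expect_equal(res$ages[res$calibrations$node[1]], 55.54, tolerance = 1e-10)
  expect_equal(res$ages[seq_len(nt)], rep(0, nt))
})

test_that("a two-taxon ingroup with a root calibration dates both paths at it", {
  tre <- ape::read.tree(text = "((a:0.1,b:0.14):0.2,OUT:0.5);")
  cal <- tibble::tibble(taxon_a = "a", taxon_b = "b", age = 55.54)
  res <- reltime_date(tre, "OUT", cal)
  td <- tidy(res)
  expect_equal(dplyr::filter(td, !is_tip)$age, 55.54)
  expect_equal(dplyr::filter(td, is_tip)$age, c(0, 0))
})

test_that("dating is invariant to uniform branch-length scaling", {
  ct <- simulate_clock_tree(10, rate_sigma = 0.2, seed = 4)
  tre <- attach_outgroup(ct$subst_tree)
  tips <- ct$time_tree$tip.label
  cal <- tibble::tibble(taxon_a = tips[1], taxon_b = tips[5], age = 40)
  r1 <- reltime_date(tre, "OUT", cal)
  tre2 <- tre
  tre2$edge.length <- tre2$edge.length * 7.3
  r2 <- reltime_date(tre2, "OUT", cal)
  expect_equal(r1$ages, r2$ages, tolerance = 1e-10)
})

test_that("ages are monotone along every root-to-tip path", {
  for (s in 1:5) {
    ct <- simulate_clock_tree(9, rate_sigma = 0.4, seed = 30 + s)
    tre <- attach_outgroup(ct$subst_tree)
    tips <- ct$time_tree$tip.label
    cal <- tibble::tibble(taxon_a = tips[1], taxon_b = tips[2], age = 30)
    res <- reltime_date(tre, "OUT", cal)
    edge <- res$tree$edge
    expect_true(all(res$ages[edge[, 1]] >= res$ages[edge[, 2]] - 1e-12))
  }
})

test_that("relative heights recover truth under lognormal rate noise", {
  cors <- vapply(1:20, function(s) {
    ct <- simulate_clock_tree(12, rate_sigma = 0.2, seed = s)
    tre <- attach_outgroup(ct$subst_tree)
    tips <- ct$time_tree$tip.label
    cal <- tibble::tibble(taxon_a = tips[1], taxon_b = tips[2], age = 50)
    res <- reltime_date(tre, "OUT", cal)
    nt <- ape::Ntip(ct$time_tree)
    key_true <- clade_keys(ct$time_tree)
    key_est <- clade_keys(res$tree)
    est <- res$relative_heights[(nt + 1):(nt + res$tree$Nnode)]
    stats::cor(est[match(key_true, key_est)],
               ct$true_heights[(nt + 1):(nt + ct$time_tree$Nnode)])
  }, numeric(1))
  expect_gte(mean(cors), 0.95)
})

test_that("calibration validation catches tips and conflicts", {
  tre <- ape::read.tree(text = "(((a:1,b:1):1,(c:1.5,d:0.5):0.5):1,OUT:4);")
  expect_error(
    reltime_date(tre, "OUT",
                 tibble::tibble(taxon_a = "a", taxon_b = "a", age = 10)),
    "calibration on a tip")
  # two point calibrations that no single scale satisfies within 10%
  cal_bad <- tibble::tibble(taxon_a = c("a", "a"), taxon_b = c("b", "d"),
                            age = c(10, 100))
  expect_error(reltime_date(tre, "OUT", cal_bad), "constraint-conflict")
  # compatible pair: least-squares scale satisfies both
  h <- reltime_date(tre, "OUT",
                    tibble::tibble(taxon_a = "a", taxon_b = "b", age = 10))
  root_age <- glance(h)$root_age
  cal_ok <- tibble::tibble(taxon_a = c("a", "a"), taxon_b = c("b", "d"),
                           age = c(10, root_age))
  r <- reltime_date(tre, "OUT", cal_ok)
  expect_equal(r$ages[r$calibrations$node[1]], 10, tolerance = 1)
  # interval calibration bounds the scale
  cal_int <- tibble::tibble(taxon_a = "a", taxon_b = "d",
                            age_min = 40, age_max = 60)
  ri <- reltime_date(tre, "OUT", cal_int)
  age <- ri$ages[ri$calibrations$node[1]]
  expect_true(age >= 40 && age <= 60)
  expect_error(
    reltime_date(tre, "OUT",
                 tibble::tibble(taxon_a = c("a", "c"), taxon_b = c("b", "d"),
                                age_min = c(50, 1), age_max = c(60, 2))),
    "incompatible")
  expect_error(reltime_date(tre, "BAD", cal_int), "not in tree")
})

test_that("bootstrap CIs are seeded, reproducible and bracket the estimate", {
  ct <- simulate_clock_tree(6, rate_sigma = 0.1, seed = 12, depth_scale = 0.1)
  tre <- attach_outgroup(ct$subst_tree)
  ev <- evolve_alignment(evol_spec(tre, substitution_model("K2P", kappa = 3),
                                   2000, seed = 12))
  tips <- ct$time_tree$tip.label
  cal <- tibble::tibble(taxon_a = tips[1], taxon_b = tips[2], age = 30)
  b1 <- reltime_bootstrap(ev$alignment, tre, "OUT", cal, replicates = 30,
                          seed = 99)
  b2 <- reltime_bootstrap(ev$alignment, tre, "OUT", cal, replicates = 30,
                          seed = 99)
  expect_equal(b1$ci, b2$ci)
  expect_gt(b1$n_effective, 25)
  inner <- dplyr::filter(b1$ci, age > 0)
  expect_true(all(inner$lower <= inner$upper))
})
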