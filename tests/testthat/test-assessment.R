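# Nearest-site assignment, individual assessment, subgroup contrasts, IDW
# surfaces and goodness-of-fit grading.

three_sites <- function() {
  data.frame(site_id = c("A", "B", "C"), x = c(1, 0, 4), y = c(0, 3, 0),
             bap_eq = c(4, 8, 20))
}

test_that("nearest-site assignment is Euclidean with lexicographic ties", {
  sites <- three_sites()
  at_site <- assign_nearest_site(data.frame(x = 0, y = 3), sites)
  expect_equal(at_site$site_id, "B")
  expect_equal(at_site$bap_eq, 8)
  # (0,0): distance 1 to A, 3 to B
  expect_equal(assign_nearest_site(data.frame(x = 0, y = 0), sites)$site_id,
               "A")
  # equidistant between A(1,0) and C(4,0) at x = 2.5 -> smaller id wins
  tie <- assign_nearest_site(data.frame(x = 2.5, y = 0), sites)
  expect_equal(tie$site_id, "A")
  # pre-assigned site ids pass through unchanged
  pre <- assign_nearest_site(data.frame(site_id = "C"), sites)
  expect_equal(pre$bap_eq, 20)
  expect_error(assign_nearest_site(data.frame(x = 0, y = 0), sites[0, ]),
               "at least one site")
})

test_that("individual assessment reproduces the hand-computed ILCR", {
  sites <- data.frame(site_id = "S", x = 0, y = 0, bap_eq = 10)
  one <- data.frame(id = "p1", age = 30, sex = "male", area = "urban",
                    height_cm = 171, bw_kg = 64,
                    ir_lpm = convert_ir(16, "m3/day", "L/min"),
                    x = 1, y = 1)
  out <- assess_individuals(one, sites)
  expect_equal(out$ilcr, 5.943571e-06, tolerance = 1e-6)
  expect_equal(as.character(out$risk_class), "exceeds_acceptable")
  expect_equal(attr(out, "summary")$n, 1)
})

test_that("a shared site collapses risk variation to BW and IR", {
  sites <- data.frame(site_id = "S", x = 0, y = 0, bap_eq = 12)
  n <- 50
  set.seed(2)
  ppl <- data.frame(id = sprintf("p%02d", 1:n), age = 30, sex = "female",
                    area = "urban", height_cm = 160,
                    bw_kg = rlnorm(n, 4.1, 0.2),
                    ir_lpm = rlnorm(n, 2.4, 0.2), x = runif(n), y = runif(n))
  out <- assess_individuals(ppl, sites)
  expect_true(all(out$bap_eq == 12))
  expect_equal(out$ilcr,
               compute_ilcr(12, convert_ir(ppl$ir_lpm, "L/min", "m3/day"),
                            ppl$bw_kg))
  # deterministic given inputs: row order does not change anyone's risk
  shuf <- sample(n)
  out2 <- assess_individuals(ppl[shuf, ], sites)
  expect_equal(out2$ilcr, out$ilcr[shuf])
})

test_that("missing measured IR falls back to the BMR estimate", {
  sites <- data.frame(site_id = "S", x = 0, y = 0, bap_eq = 10)
  p <- data.frame(id = "p1", age = 30, sex = "male", area = "urban",
                  height_cm = 171, bw_kg = 67.7, x = 0, y = 0)
  out <- assess_individuals(p, sites)
  expect_equal(out$ir_m3d,
               convert_ir(estimate_ir_from_bmr(67.7, 171, 30, "male"),
                          "L/min", "m3/day"))
})

test_that("subgroup contrasts match a brute-force rank computation", {
  ppl <- data.frame(ilcr = c(1, 2, 3, 10, 20, 30) * 1e-6,
                    grp = rep(c("g1", "g2"), each = 3))
  cmp <- compare_subgroups(ppl, "grp")
  # brute force: ranks 1..6, H = 12/(n(n+1)) * sum n_i (Rbar_i - (n+1)/2)^2
  r <- rank(ppl$ilcr)
  h <- 12 / (6 * 7) * (3 * (mean(r[1:3]) - 3.5)^2 + 3 * (mean(r[4:6]) - 3.5)^2)
  expect_equal(cmp$statistic, h)
  expect_equal(cmp$groups$geomean, c(geomean(ppl$ilcr[1:3]),
                                     geomean(ppl$ilcr[4:6])))
  # identical groups: no evidence of difference
  same <- data.frame(ilcr = rep(c(1e-6, 2e-6, 3e-6), 2),
                     grp = rep(c("a", "b"), each = 3))
  cmp0 <- compare_subgroups(same, "grp")
  expect_equal(cmp0$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp0$p_value, 1)
  expect_error(compare_subgroups(data.frame(ilcr = 1:4, grp = "only"), "grp"),
               "two groups")
})

test_that("rural participants carry higher risk in the default scenario", {
  spec <- scenario_spec(n_participants = 600, seed = 12)
  sites <- gen_sites(spec)
  ppl <- assess_individuals(gen_participants(spec, sites), sites)
  cmp <- compare_subgroups(ppl, "area")
  g <- cmp$groups
  expect_gt(g$geomean[g$group == "rural"], g$geomean[g$group == "urban"])
})

test_that("IDW interpolation is exact at sites and symmetric at midpoints", {
  sites <- data.frame(site_id = c("A", "B"), x = c(0, 2), y = c(0, 0),
                      bap_eq = c(4, 8))
  for (pw in c(0.5, 1, 2, 5)) {
    at_site <- idw_surface(sites, data.frame(x = 0, y = 0), power = pw)
    expect_equal(at_site$value, 4)
    mid <- idw_surface(sites, data.frame(x = 1, y = 0), power = pw)
    expect_equal(mid$value, 6)
  }
  # large power approaches nearest-site assignment
  tri <- three_sites()
  node <- data.frame(x = 0.5, y = 0.4)
  hard <- idw_surface(tri, node, power = 60)$value
  nearest <- assign_nearest_site(node, tri)$bap_eq
  expect_equal(hard, nearest, tolerance = 1e-6)
  grid <- idw_surface(tri, list(xlim = c(0, 4), ylim = c(0, 3),
                                nx = 5, ny = 4))
  expect_equal(nrow(grid), 20)
  expect_true(all(grid$value >= min(tri$bap_eq) &
                    grid$value <= max(tri$bap_eq)))
})

test_that("goodness-of-fit ratios reproduce printed comparison arithmetic", {
  x <- rlnorm(40, -12, 0.5)
  self <- goodness_of_fit(x, x)
  expect_equal(self$mean_ratio, 1)
  expect_equal(self$median_ratio, 1)
  expect_equal(self$sd_ratio, 1)
  expect_equal(self$span_difference, 0)
  # mean ratio on the reported mean pair: 1.63e-5 / 6.25e-6 = 2.6
  means <- goodness_of_fit(rep(6.25e-6, 3), rep(1.63e-5, 3))
  expect_equal(means$mean_ratio, 2.6, tolerance = 0.005)
  # SD ratio on the reported SD pair: 2.37e-5 / 6.40e-6 = 3.7
  pair <- function(s) 1e-4 + c(-1, 1) * s / sqrt(2)
  sds <- goodness_of_fit(pair(6.40e-6), pair(2.37e-5))
  expect_equal(sds$sd_ratio, 3.7, tolerance = 0.005)
  expect_error(goodness_of_fit(numeric(0), x), "positive|non-empty")
})

test_that("clustered exposure produces a multimodal risk distribution", {
  spec <- scenario_spec(seed = 3)
  sites <- gen_sites(spec)
  ppl <- assess_individuals(gen_participants(spec, sites), sites)
  expect_gte(length(risk_density(ppl$ilcr)$modes), 2)
})
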