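test_that("holo masses follow the proton-displacement arithmetic", {
  apo <- 25377.62
  expect_equal(holo_mass(apo, c()), apo)
  expect_lt(abs(holo_mass(apo, c(Zn = 20)) - (apo + 20 * ZN_INC)), 1e-9)
  expect_lt(abs(holo_mass(apo, c(Zn = 20)) - 26644.9), 0.05)
  expect_lt(abs(holo_mass(apo, c(Cu = 1)) - apo - 62.538), 0.001)
  expect_lt(abs(holo_mass(apo, c(Cd = 2, S2 = 1)) -
                (apo + 2 * CD_INC + 32.065)), 1e-9)
  expect_error(holo_mass(apo, c(Xx = 1)), "unknown metal")
  expect_error(holo_mass(-1, c(Zn = 1)))
})

test_that("holo mass is strictly increasing in every coordinate", {
  apo <- 10000
  for (el in c("Zn", "Cd", "Cu", "S2")) {
    masses <- vapply(0:5, function(n) holo_mass(apo, setNames(n, el)), 0)
    expect_true(all(diff(masses) > 0))
  }
})

test_that("assign_peaks inverts holo_mass for in-bounds stoichiometries", {
  apo <- 25377.62
  set.seed(2)
  for (i in 1:25) {
    st <- c(Zn = sample(0:20, 1), Cd = sample(0:10, 1))
    a <- assign_peaks(holo_mass(apo, st), apo,
                      metals = default_metals(c("Zn", "Cd")), max_total = 35)
    top <- a[[1]]$candidates[1, ]
    expect_equal(c(Zn = top$Zn, Cd = top$Cd), st)
    expect_lt(abs(top$mass_error_da), 1e-6)
  }
})

test_that("an exact Zn ladder is assigned with zero error", {
  apo <- 25377.62
  peaks <- vapply(17:21, function(n) holo_mass(apo, c(Zn = n)), 0)
  res <- best_assignments(assign_peaks(peaks, apo, metals = default_metals("Zn")))
  expect_equal(res$Zn, 17:21)
  expect_equal(res$best_label, paste0("Zn", 17:21))
  expect_true(all(abs(res$mass_error_da) < 1e-9))
  # the apo peak itself maps to the empty stoichiometry
  res0 <- best_assignments(assign_peaks(apo, apo, metals = default_metals("Zn")))
  expect_equal(res0$best_label, "apo")
})

test_that("empty peak lists and bad apo masses are handled per contract", {
  expect_length(assign_peaks(numeric(0), 1000), 0L)
  expect_error(assign_peaks(1000, 0), "invalid input")
  expect_error(assign_peaks(1000, -5), "invalid input")
})

test_that("Zn/Cu composites are flagged exactly when the routes are indiscernible", {
  apo <- 25377.62
  tol <- 0.001
  # the flag must agree with direct arithmetic over a range of loadings
  for (n in c(2L, 5L, 15L, 30L, 45L)) {
    peak <- apo + n * CU_INC
    a <- assign_peaks(peak, apo, metals = default_metals(c("Zn", "Cu")),
                      max_total = 50, tolerance_rel = tol)
    cand <- a[[1]]$candidates
    zn_only <- cand[cand$Zn > 0 & cand$Cu == 0, ]
    cu_only <- cand[cand$Cu > 0 & cand$Zn == 0, ]
    expected <- nrow(zn_only) > 0 && nrow(cu_only) > 0 &&
      abs(zn_only$theoretical_mass[1] - cu_only$theoretical_mass[1]) <= tol * peak
    expect_equal(a[[1]]$ambiguous_ZnCu, expected)
    if (expected) expect_equal(a[[1]]$best_label, sprintf("M%d", n))
  }
  # a single-metal enumeration can never fire the composite flag
  b <- assign_peaks(apo + 10 * ZN_INC, apo, metals = default_metals("Zn"))
  expect_false(b[[1]]$ambiguous_ZnCu)
})

test_that("stoichiometry recovery survives realistic mass noise", {
  apo <- 25377.62
  set.seed(6)
  n_pk <- 200
  truth <- sample(5:40, n_pk, replace = TRUE)
  peaks <- vapply(truth, function(n) holo_mass(apo, c(Zn = n)), 0)
  peaks <- peaks * (1 + rnorm(n_pk, 0, 2e-4))
  res <- best_assignments(assign_peaks(peaks, apo, metals = default_metals("Zn"),
                                       max_total = 50))
  expect_gte(mean(res$Zn == truth), 0.99)
})

test_that("peak CSV round-trips", {
  df <- data.frame(mass_da = c(25377.6, 26644.9), intensity = c(10, 5))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  back <- read_peaklist(f)
  expect_equal(back$mass_da, df$mass_da)
  expect_equal(back$intensity, df$intensity)
  # intensity column is optional
  write.csv(df["mass_da"], f, row.names = FALSE)
  expect_equal(read_peaklist(f)$intensity, c(1, 1))
  expect_error(read_peaklist({
    f2 <- tempfile(fileext = ".csv"); write.csv(data.frame(x = 1), f2, row.names = FALSE); f2
  }), "mass_da")
})

test_that("sulfur-based protein quantitation gives metal-per-protein ratios", {
  icp <- metal_per_protein(c(S = 114e-6, Zn = 40e-6), 57)
  expect_equal(icp$protein_concentration, 2e-6)
  expect_equal(unname(icp$metal_per_protein[["Zn"]]), 20.0)
  icp2 <- metal_per_protein(c(S = 114e-6, Cd = 48.84e-6), 57)
  expect_equal(unname(icp2$metal_per_protein[["Cd"]]), 24.42)
  icp3 <- metal_per_protein(c(S = 114e-6, Cu = 0), 57)
  expect_equal(unname(icp3$metal_per_protein[["Cu"]]), 0)
  expect_error(metal_per_protein(c(S = 0, Zn = 1e-6), 57), "division undefined")
  expect_error(metal_per_protein(c(Zn = 1e-6), 57), "include S")
})
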