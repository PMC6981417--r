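test_that("constructed diagnostic fragments drive the positional call", {
  # terminal acetyl: acetylated B1 (332.10) present, plain B1 absent
  term_spec <- as_spectrum(data.frame(mz = c(332.10, 536.50),
                                      intensity = c(80, 100)))
  loc <- localize_acetyl(term_spec, "OAcGD3", "16:0")
  expect_equal(loc$call, "Neu5Ac2")

  # inner acetyl: plain B1 plus acetylated Y-side fragment
  y3_inner <- predict_fragments("OAcGD3", "16:0", "Neu5Ac1")
  y3_mz <- y3_inner$mz[y3_inner$label == "Y3"]
  inner_spec <- as_spectrum(data.frame(mz = c(290.09, y3_mz),
                                       intensity = c(60, 40)))
  loc2 <- localize_acetyl(inner_spec, "OAcGD3", "16:0")
  expect_equal(loc2$call, "Neu5Ac1")
})

test_that("no diagnostic overlap yields an explained ambiguous call", {
  spec <- as_spectrum(data.frame(mz = c(536.50, 699.56),  # ceramide Y ions only
                                 intensity = c(10, 5)))
  loc <- localize_acetyl(spec, "OAcGD3", "16:0")
  expect_equal(loc$call, "ambiguous")
  expect_match(loc$status, "no diagnostic")
  expect_true(is.na(loc$margin))
})

test_that("near-equal evidence for both positions is called ambiguous", {
  # equal intensity on the plain and acetylated B1 gives margin 1 < 2
  spec <- as_spectrum(data.frame(mz = c(290.09, 332.10),
                                 intensity = c(100, 100)))
  loc <- localize_acetyl(spec, "OAcGD3", "16:0")
  expect_equal(loc$call, "ambiguous")
  expect_equal(loc$margin, 1)
  # raising one side above the margin threshold resolves the call
  spec2 <- as_spectrum(data.frame(mz = c(290.09, 332.10),
                                  intensity = c(100, 250)))
  expect_equal(localize_acetyl(spec2, "OAcGD3", "16:0")$call, "Neu5Ac2")
})

test_that("localization needs an acetylated candidate and fragments", {
  s <- as_spectrum(data.frame(mz = 290.09, intensity = 1))
  expect_error(localize_acetyl(s, "GD3", "16:0"), "O-acetylated")
  expect_error(localize_acetyl(s[0, ], "OAcGD3", "16:0"), "Empty fragment")
})

test_that("noise-free simulated spectra localize perfectly at full coverage", {
  cases <- list(c("OAcGD3", "Neu5Ac1"), c("OAcGD3", "Neu5Ac2"),
                c("OAcGD2", "Neu5Ac1"), c("OAcGD2", "Neu5Ac2"),
                c("OAcGT3", "Neu5Ac1"), c("OAcGT3", "Neu5Ac2"),
                c("OAcGT3", "Neu5Ac3"), c("OAcGT2", "Neu5Ac3"))
  for (cs in cases) {
    fr <- simulate_msms(cs[1], "16:0", acetyl_position = cs[2], seed = 5)
    loc <- localize_acetyl(fr, cs[1], "16:0")
    expect_equal(loc$call, cs[2])
  }
})

test_that("tidy and glance summarize a localization", {
  fr <- simulate_msms("OAcGD3", "16:0", acetyl_position = "Neu5Ac2", seed = 2)
  loc <- localize_acetyl(fr, "OAcGD3", "16:0")
  td <- tidy(loc)
  expect_equal(td$position, c("Neu5Ac1", "Neu5Ac2"))
  expect_equal(td$call, c(FALSE, TRUE))
  gl <- glance(loc)
  expect_equal(gl$call, "Neu5Ac2")
  expect_equal(gl$n_positions, 2L)
})

test_that("isobaric intensity splits follow candidate-unique evidence", {
  lib <- enumerate_library()
  cands <- lib[(lib$species == "OAcGD2" & lib$acyl == "16:0" &
                  lib$n_dehydrations == 1L) |
               (lib$species == "OAcGM1" & lib$acyl == "24:0" &
                  lib$n_dehydrations == 0L), ]
  expect_equal(nrow(cands), 2)

  # only OAcGM1-core fragments observed: full share to OAcGM1
  gm1_fr <- predict_fragments("OAcGM1", "24:0")
  gd2_fr <- predict_fragments("OAcGD2", "16:0")
  only_gm1 <- gm1_fr$mz[vapply(gm1_fr$mz,
                               function(m) all(abs(gd2_fr$mz - m) > 0.5),
                               logical(1))]
  s <- as_spectrum(data.frame(mz = only_gm1, intensity = 10))
  sh <- split_isobaric_intensity(s, cands)
  expect_equal(sh$share[sh$species == "OAcGM1"], 1)
  expect_equal(sh$share[sh$species == "OAcGD2"], 0)

  # proportionality: manufactured unique intensities 30 vs 10 -> 0.75 / 0.25
  only_gd2 <- gd2_fr$mz[vapply(gd2_fr$mz,
                               function(m) all(abs(gm1_fr$mz - m) > 0.5),
                               logical(1))]
  s2 <- as_spectrum(data.frame(mz = c(only_gd2[1], only_gm1[1]),
                               intensity = c(30, 10)))
  sh2 <- split_isobaric_intensity(s2, cands)
  expect_equal(sh2$share[sh2$species == "OAcGD2"], 0.75)
  expect_equal(sh2$share[sh2$species == "OAcGM1"], 0.25)
  expect_equal(sum(sh2$share), 1)

  # permutation equivariance
  sh_rev <- split_isobaric_intensity(s2, cands[2:1, ])
  expect_equal(sh_rev$share[match(sh2$species, sh_rev$species)], sh2$share)

  # no unique evidence -> equal split with a warning flag
  s3 <- as_spectrum(data.frame(mz = 3000, intensity = 1))
  expect_warning(sh3 <- split_isobaric_intensity(s3, cands), "equally")
  expect_equal(sh3$share, c(0.5, 0.5))
  expect_equal(unique(sh3$note), "equal split")
})

test_that("a known 60/40 mixture is recovered within 0.1 at 5% noise", {
  lib <- enumerate_library()
  cands <- lib[(lib$species == "OAcGD2" & lib$acyl == "16:0" &
                  lib$n_dehydrations == 1L) |
               (lib$species == "OAcGM1" & lib$acyl == "24:0" &
                  lib$n_dehydrations == 0L), ]
  errs <- vapply(1:20, function(seed) {
    a <- simulate_msms("OAcGD2", "16:0", seed = seed, noise_sd = 0.05,
                       base_intensity = 60)
    b <- simulate_msms("OAcGM1", "24:0", seed = seed + 1000,
                       noise_sd = 0.05, base_intensity = 40)
    mix <- as_spectrum(rbind(as.data.frame(a), as.data.frame(b)))
    sh <- split_isobaric_intensity(mix, cands)
    sh$share[sh$species == "OAcGD2"] - 0.6
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.1)
})
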