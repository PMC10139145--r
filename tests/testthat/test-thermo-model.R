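test_that("fraction unfolded is 1/2 at Tm, saturates far above, matches the closed form", {
  for (sp in speciesLibrary())
    expect_equal(fractionUnfolded(sp, sp@tm), 0.5, tolerance = 1e-12)

  hsa600 <- ProteinSpecies("HSA", tm = 75.1, dh = 600)
  expect_gte(fractionUnfolded(hsa600, 75.1 + 60), 0.999)
  # frozen value from an independent 30-digit evaluation of
  # 1 / (1 + exp(dH (1 - T/Tm) / (R T))), T in kelvin
  expect_equal(fractionUnfolded(hsa600, 73.1), 0.23202307869421037,
               tolerance = 1e-14)
  expect_equal(fractionUnfolded(hsa600, 40), 8.1833649701702131e-11,
               tolerance = 1e-12)
})

test_that("fraction unfolded is monotone in temperature and rejects bad input", {
  sp <- getSpecies("LYZ")
  tt <- seq(30, 100, by = 0.05)
  expect_true(all(diff(fractionUnfolded(sp, tt)) >= 0))
  expect_error(fractionUnfolded(sp, NaN), "finite")
  expect_error(fractionUnfolded(sp, Inf), "finite")
})

test_that("ligand modifiers shift only the listed species and are idempotent", {
  ctrl <- mixturePreset("CONTROL", ligands = list("MYRISTATE"))
  shifted <- applyLigands(ctrl)
  tms <- vapply(shifted@species, slot, numeric(1), "tm")
  names(tms) <- vapply(shifted@species, slot, "", "name")
  expect_equal(tms[["HSA"]], 80.3)
  expect_equal(tms[["LYZ"]], 55.6)
  expect_equal(tms[["LCN1"]], 69.4)
  expect_equal(tms[["IGA"]], 72.9)
  expect_equal(tms[["LTF"]], 67.4)
  expect_equal(shifted@concentrations, ctrl@concentrations)
  # absolute-replacement shifts are idempotent
  again <- applyLigands(MixtureSpec(shifted@species, shifted@concentrations,
                                    ligands = list(getLigand("MYRISTATE"))))
  expect_equal(unname(vapply(again@species, slot, numeric(1), "tm")),
               unname(tms))

  fe <- applyLigands(mixturePreset("CONTROL", ligands = list("FE3")))
  feTms <- stats::setNames(vapply(fe@species, slot, numeric(1), "tm"),
                           vapply(fe@species, slot, "", "name"))
  expect_equal(feTms[["LTF"]], 95.0)
  expect_equal(feTms[["HSA"]], 75.1)
})

test_that("latanoprost leaves the mixture unchanged", {
  plain <- applyLigands(mixturePreset("CONTROL"))
  lat <- applyLigands(mixturePreset("CONTROL", ligands = list("LATANOPROST")))
  expect_equal(vapply(lat@species, slot, numeric(1), "tm"),
               vapply(plain@species, slot, numeric(1), "tm"))
})

test_that("delta shifts add to Tm and unknown species are a configuration error", {
  lig <- LigandModifier("CUSTOM", list(HSA = list(dtm = -3)))
  mix <- MixtureSpec(getSpecies("HSA"), 100, ligands = list(lig))
  expect_equal(applyLigands(mix)@species[[1]]@tm, 75.1 - 3)
  bad <- LigandModifier("BAD", list(NOPE = list(tm = 80)))
  expect_error(applyLigands(MixtureSpec(getSpecies("HSA"), 100,
                                        ligands = list(bad))),
               "unknown species")
})

test_that("mixture channel signals are the sum of the single-species signals", {
  ctrl <- mixturePreset("CONTROL")
  mixRun <- simulateScan(ctrl, noiseSigmaRel = 0)
  sum330 <- 0; sum350 <- 0
  for (i in seq_along(ctrl@species)) {
    one <- simulateScan(MixtureSpec(ctrl@species[[i]],
                                    ctrl@concentrations[i]),
                        noiseSigmaRel = 0)
    sum330 <- sum330 + f330(one)
    sum350 <- sum350 + f350(one)
  }
  expect_equal(f330(mixRun), sum330, tolerance = 1e-12)
  expect_equal(f350(mixRun), sum350, tolerance = 1e-12)
})

test_that("the ratio curve of a single species is concentration-invariant and monotone", {
  r1 <- simulateScan(MixtureSpec(getSpecies("HSA"), 10), noiseSigmaRel = 0)
  r2 <- simulateScan(MixtureSpec(getSpecies("HSA"), 500), noiseSigmaRel = 0)
  expect_equal(f350(r1) / f330(r1), f350(r2) / f330(r2), tolerance = 1e-14)
  expect_true(all(diff(f350(r1) / f330(r1)) >= 0))
})

test_that("seeded scans are bit-identical and noise settings are validated", {
  ctrl <- mixturePreset("CONTROL")
  a <- simulateScan(ctrl, noiseSigmaRel = 0.002, seed = 42L)
  b <- simulateScan(ctrl, noiseSigmaRel = 0.002, seed = 42L)
  expect_identical(f330(a), f330(b))
  expect_identical(f350(a), f350(b))
  c <- simulateScan(ctrl, noiseSigmaRel = 0.002, seed = 43L)
  expect_false(identical(f330(a), f330(c)))
  expect_error(simulateScan(ctrl, noiseSigmaRel = -0.1), ">= 0")
  expect_error(MixtureSpec(list(), numeric(0)), "at least one component")
})

test_that("every library species and reachable ligand variant round-trips its Tm", {
  variants <- list()
  for (nm in names(speciesLibrary()))
    variants[[nm]] <- getSpecies(nm)
  # ligand-shifted species with Tm <= 94 (the Fe3+ LTF endpoint sits at the
  # scan limit and is boundary-censored instead)
  myr <- getLigand("MYRISTATE")
  for (nm in names(myr@shifts)) {
    sp <- getSpecies(nm); sp@tm <- myr@shifts[[nm]]$tm
    variants[[paste0(nm, "_MYR")]] <- sp
  }
  for (sp in variants) {
    run <- simulateScan(MixtureSpec(sp, 100), noiseSigmaRel = 0)
    pp <- detectFromRun(run)
    apex <- peakTemps(pp)[!is.na(peakTemps(pp))]
    expect_length(apex, 1L)
    expect_lte(abs(apex - sp@tm), 0.1)
  }
})

test_that("library constants load from the packaged data file", {
  lib <- speciesLibrary()
  expect_named(lib, c("LYZ", "LCN1", "IGA", "HSA", "LTF"))
  expect_equal(vapply(lib, slot, numeric(1), "tm"),
               c(LYZ = 67.8, LCN1 = 69.4, IGA = 72.9, HSA = 75.1, LTF = 67.4))
  ctrl <- mixturePreset("CONTROL")
  expect_equal(sum(ctrl@concentrations), 140 + 110 + 50 + 30 + 100)
  expect_error(getSpecies("ALB"), "unknown species")
  expect_error(mixturePreset("HEALTHY"), "unknown preset")
})
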