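#' Built-in tear-protein library, ligand table and mixture presets
#'
#' The package ships thermodynamic parameters for the five core tear
#' proteins -- lysozyme C (LYZ), lipocalin-1 (LCN1), immunoglobulin A (IGA),
#' serum albumin (HSA) and lactotransferrin (LTF) -- with melting
#' temperatures 67.8, 69.4, 72.9, 75.1 and 67.4 degrees C, a shared van't
#' Hoff enthalpy default of 600 kJ/mol, and the default emission model.
#' The ligand table holds the saturating Tm shifts of myristic acid
#' (HSA to 80.3, LYZ to 55.6 degrees C), ferric iron (LTF to 95.0 degrees C)
#' and latanoprost (no effect). Two mixture presets reproduce the
#' physiological compositions used for healthy ("CONTROL": HSA 140, LTF 110,
#' LYZ 50, IGA 30, LCN1 100 ug/mL) and glaucomatous ("POAG": HSA 110,
#' LTF 150, LYZ 30, IGA 30, LCN1 60 ug/mL) tear-relevant mixtures.
#'
#' @return `speciesLibrary()`: named list of [ProteinSpecies-class];
#'   `ligandLibrary()`: named list of [LigandModifier-class];
#'   `getSpecies(name)` / `getLigand(name)`: single entries;
#'   `mixturePreset(name, ligands)`: a [MixtureSpec-class].
#' @examples
#' names(speciesLibrary())
#' getSpecies("HSA")
#' mixturePreset("CONTROL")
#' @export
speciesLibrary <- function() {
  lib <- .tfdpLibrary()
  out <- lapply(lib$species, function(s)
    ProteinSpecies(s$name, tm = s$tm, dh = s$dh, a330 = s$a330,
                   a350 = s$a350, d330 = s$d330, d350 = s$d350,
                   slope330 = s$slope330, slope350 = s$slope350))
  names(out) <- vapply(lib$species, `[[`, "", "name")
  out
}

#' @rdname speciesLibrary
#' @export
ligandLibrary <- function() {
  lib <- .tfdpLibrary()
  out <- lapply(lib$ligands, function(l) LigandModifier(l$ligand, l$shifts))
  names(out) <- vapply(lib$ligands, `[[`, "", "ligand")
  out
}

#' @rdname speciesLibrary
#' @param name species, ligand or preset identifier (case-insensitive).
#' @export
getSpecies <- function(name) {
  lib <- speciesLibrary()
  key <- toupper(name)
  if (!key %in% names(lib))
    stop("unknown species '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  lib[[key]]
}

#' @rdname speciesLibrary
#' @export
getLigand <- function(name) {
  lib <- ligandLibrary()
  key <- toupper(name)
  if (!key %in% names(lib))
    stop("unknown ligand '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  lib[[key]]
}

#' @rdname speciesLibrary
#' @param ligands list of [LigandModifier-class] (or ligand names) attached
#'   to the preset mixture.
#' @export
mixturePreset <- function(name, ligands = list()) {
  lib <- .tfdpLibrary()
  key <- toupper(name)
  if (!key %in% names(lib$presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(lib$presets), collapse = ", "))
  comp <- lib$presets[[key]]
  ligands <- lapply(ligands, function(l)
    if (is.character(l)) getLigand(l) else l)
  MixtureSpec(speciesLibrary()[names(comp)], unlist(comp),
              ligands = ligands, name = key)
}

.tfdpLibrary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "tear_protein_library.json",
                          package = "tfdp", mustWork = TRUE)
      cache <<- jsonlite::read_json(path)
    }
    cache
  }
})

#' Equilibrium fraction unfolded of a two-state protein
#'
#' Two-state (folded/unfolded) equilibrium with a temperature-independent
#' van't Hoff enthalpy: the free energy of unfolding is
#' `dG(T) = dH * (1 - T/Tm)` (temperatures in kelvin), giving
#' `fU(T) = 1 / (1 + exp(dG(T) / (R T)))`. The fraction is exactly 1/2 at
#' Tm and is monotonically non-decreasing in temperature.
#'
#' @param species a [ProteinSpecies-class].
#' @param temperature numeric vector, degrees C.
#' @return Fraction unfolded in [0, 1], one value per temperature.
#' @examples
#' hsa <- getSpecies("HSA")
#' fractionUnfolded(hsa, c(65, 75.1, 85))
#' @export
setGeneric("fractionUnfolded",
           function(species, temperature) standardGeneric("fractionUnfolded"))

#' @rdname fractionUnfolded
setMethod("fractionUnfolded", "ProteinSpecies", function(species, temperature) {
  if (!all(is.finite(temperature)))
    stop("temperature must be finite")
  tK <- temperature + .KELVIN
  tmK <- species@tm + .KELVIN
  dG <- species@dh * (1 - tK / tmK)
  1 / (1 + exp(dG / (.R_GAS * tK)))
})

#' Apply ligand modifiers to a mixture
#'
#' Resolves the ligand state of a mixture: each ligand's shift table is
#' applied to the matching species (absolute replacement Tm or additive
#' delta), concentrations are untouched, and the returned mixture carries an
#' empty ligand list (shifts are baked into the species). Binding is modelled
#' as saturating -- a listed ligand confers its full end-state shift. The
#' operation is idempotent for absolute-replacement shifts.
#'
#' @param mixture a [MixtureSpec-class].
#' @return A [MixtureSpec-class] with shifted species.
#' @examples
#' applyLigands(mixturePreset("CONTROL", ligands = list("MYRISTATE")))
#' @export
setGeneric("applyLigands", function(mixture) standardGeneric("applyLigands"))

#' @rdname applyLigands
setMethod("applyLigands", "MixtureSpec", function(mixture) {
  species <- mixture@species
  present <- vapply(species, slot, "", "name")
  known <- union(present, names(speciesLibrary()))
  for (lig in mixture@ligands) {
    unknown <- setdiff(names(lig@shifts), known)
    if (length(unknown))
      stop("ligand ", lig@ligand, " references unknown species: ",
           paste(unknown, collapse = ", "))
    # shifts for known species absent from this mixture are inapplicable
    for (sp in intersect(names(lig@shifts), present)) {
      i <- match(sp, present)
      shift <- lig@shifts[[sp]]
      newTm <- if (identical(names(shift), "tm")) shift[[1]]
               else species[[i]]@tm + shift[[1]]
      s <- species[[i]]
      s@tm <- newTm
      validObject(s)
      species[[i]] <- s
    }
  }
  MixtureSpec(species, mixture@concentrations, ligands = list(),
              name = mixture@name)
})

#' Simulate a nanoDSF melting scan of a protein mixture
#'
#' Forward model: each component contributes independently (linear
#' superposition) to both channels,
#' `F_lambda(T) = sum_i c_i (1 + beta_i (T - 35)) (a_i + d_i (2 fU_i(T) - 1))`,
#' where `fU_i` is the two-state fraction unfolded of component i and
#' (a, d, beta) are its per-wavelength emission mean, unfolding contrast and
#' baseline drift. Ligand modifiers attached to the mixture are applied
#' first. Multiplicative Gaussian noise `(1 + sigma_rel * eps)` is then drawn
#' independently per point and channel under the given seed;
#' `noiseSigmaRel = 0` yields a deterministic scan.
#'
#' @param mixture a [MixtureSpec-class].
#' @param grid a [TemperatureGrid-class]; default 35-95 degrees C at 0.1.
#' @param noiseSigmaRel relative noise SD (default 0.002, shot-like).
#' @param seed integer RNG seed for the noise draw.
#' @return A [NanoDSFRun-class] named after the mixture.
#' @examples
#' run <- simulateScan(mixturePreset("CONTROL"), noiseSigmaRel = 0)
#' run
#' @export
setGeneric("simulateScan",
  function(mixture, grid = TemperatureGrid(), noiseSigmaRel = 0.002,
           seed = 1L) standardGeneric("simulateScan"))

#' @rdname simulateScan
setMethod("simulateScan", "MixtureSpec",
  function(mixture, grid, noiseSigmaRel, seed) {
    if (!is.finite(noiseSigmaRel) || noiseSigmaRel < 0)
      stop("noiseSigmaRel must be >= 0")
    mix <- applyLigands(mixture)
    tt <- gridTemps(grid)
    s330 <- numeric(length(tt))
    s350 <- numeric(length(tt))
    for (i in seq_along(mix@species)) {
      sp <- mix@species[[i]]
      ci <- mix@concentrations[i]
      if (ci == 0) next
      fu <- fractionUnfolded(sp, tt)
      m <- 2 * fu - 1
      s330 <- s330 + ci * (1 + sp@slope330 * (tt - 35)) * (sp@a330 + sp@d330 * m)
      s350 <- s350 + ci * (1 + sp@slope350 * (tt - 35)) * (sp@a350 + sp@d350 * m)
    }
    if (noiseSigmaRel > 0) {
      noisy <- .withSeed(seed, {
        list(f330 = s330 * (1 + noiseSigmaRel * stats::rnorm(length(tt))),
             f350 = s350 * (1 + noiseSigmaRel * stats::rnorm(length(tt))))
      })
      s330 <- noisy$f330
      s350 <- noisy$f350
    }
    if (any(s330 <= 0) || any(s350 <= 0))
      stop("simulated intensities must be strictly positive; ",
           "reduce noiseSigmaRel or baseline drift")
    NanoDSFRun(mix@name, tt, s330, s350,
               meta = list(noiseSigmaRel = noiseSigmaRel, seed = seed))
  })
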