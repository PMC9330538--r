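#' Default wavenumber grid for the fingerprint region
#'
#' 600-1800 cm^-1 at 2 cm^-1 spacing (601 channels), the region carrying
#' most biomolecular Raman bands.
#'
#' @param lo,hi Range limits in cm^-1.
#' @param step Channel spacing in cm^-1.
#' @return Numeric wavenumber vector.
#' @export
default_grid <- function(lo = 600, hi = 1800, step = 2) seq(lo, hi, by = step)

#' Default band table for the synthetic component library
#'
#' Five components: a lipid-like and a collagen-like profile built from
#' standard band-assignment positions (C-C/C-N stretches, CH2 deformations,
#' amide bands, proline/hydroxyproline), a formalin-like contaminant, and
#' two mixed profiles with protein and nucleic-acid character. Each entry is
#' `(center, width, height)` with center and FWHM width in cm^-1 and height
#' a relative intensity. Positions are configuration, not constants: pass
#' your own table to [build_component_library()] to change them.
#'
#' @return Named list of data.frames with columns `center`, `width`, `height`.
#' @export
default_band_table <- function() {
  band <- function(center, height) {
    data.frame(center = center, width = 12, height = height)
  }
  list(
    lipid_like = band(c(1078, 1302, 1440, 1656, 1745),
                      c(0.5, 0.8, 1.0, 0.9, 0.6)),
    collagen_like = band(c(856, 938, 1246, 1454, 1667),
                         c(0.9, 0.7, 0.8, 0.6, 1.0)),
    formalin_like = band(c(907, 1041, 1238, 1492),
                         c(1.0, 0.7, 0.4, 0.5)),
    mixed_1 = band(c(1004, 1158, 1340, 1518),
                   c(1.0, 0.5, 0.7, 0.4)),
    mixed_2 = band(c(720, 782, 1095, 1578),
                   c(0.8, 1.0, 0.6, 0.7))
  )
}

#' Build a library of unit-norm component spectra from Gaussian bands
#'
#' Each component profile is a sum of Gaussian bands (FWHM parameterization)
#' evaluated on the shared wavenumber grid and scaled to unit Euclidean
#' norm. Profiles are required to be mutually distinct (pairwise cosine
#' similarity < 0.9) so that downstream unmixing is well posed.
#'
#' @param band_table Named list; one data.frame per component with columns
#'   `center`, `width` (FWHM, cm^-1) and `height`.
#' @param grid Strictly increasing wavenumber axis in cm^-1.
#' @return An object of class `component_library` with elements `names`,
#'   `profiles` (components x channels matrix, rows unit norm),
#'   `wavenumbers` and `band_table`.
#' @export
build_component_library <- function(band_table = default_band_table(),
                                    grid = default_grid()) {
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("wavenumber grid must be strictly increasing")
  }
  if (is.null(names(band_table)) || any(names(band_table) == "")) {
    stop("band_table must be a named list of components")
  }
  profiles <- matrix(0, nrow = length(band_table), ncol = length(grid),
                     dimnames = list(names(band_table), NULL))
  for (i in seq_along(band_table)) {
    bt <- band_table[[i]]
    if (is.null(bt) || nrow(bt) == 0) {
      stop("component '", names(band_table)[i], "' has an empty band list")
    }
    if (any(bt$center < min(grid)) || any(bt$center > max(grid))) {
      stop("component '", names(band_table)[i],
           "' has band centers outside the wavenumber grid")
    }
    prof <- numeric(length(grid))
    for (b in seq_len(nrow(bt))) {
      sigma <- bt$width[b] / (2 * sqrt(2 * log(2)))
      prof <- prof + bt$height[b] * exp(-(grid - bt$center[b])^2 / (2 * sigma^2))
    }
    profiles[i, ] <- prof / sqrt(sum(prof^2))
  }
  if (nrow(profiles) > 1) {
    cosine <- profiles %*% t(profiles)
    diag(cosine) <- 0
    if (max(cosine) >= 0.9) {
      pair <- which(cosine == max(cosine), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "components '%s' and '%s' are not distinct (cosine %.3f >= 0.9)",
        rownames(profiles)[pair[1]], rownames(profiles)[pair[2]], max(cosine)
      ))
    }
  }
  structure(
    list(
      names = names(band_table),
      profiles = profiles,
      wavenumbers = grid,
      band_table = band_table
    ),
    class = "component_library"
  )
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components on %d channels: %s\n",
              length(x$names), length(x$wavenumbers),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Specify a synthetic cohort design
#'
#' The default design mirrors the isogenic four-group mouse study: 67NR
#' (n = 8, non-metastatic), FARN (n = 6, intravasates only), 4T07 (n = 5,
#' extravasates but no overt growth) and 4T1 (n = 8, fully metastatic),
#' with lipid-like component abundance increasing and collagen-like
#' abundance decreasing with metastatic potential. Mouse-level mean
#' abundances are drawn around the group mean (between-mouse SD), and each
#' spectrum jitters around its mouse mean (within-mouse SD).
#'
#' @param groups data.frame with one row per group: `group`, `n_mice`, and
#'   one mean-abundance column per library component.
#' @param between_sd,within_sd Between-mouse and within-mouse abundance SDs.
#' @param spectra_per_mouse Mean of the per-mouse spectrum count
#'   distribution (Gaussian, rounded, truncated at 1).
#' @param spectra_per_mouse_sd SD of that count distribution.
#' @param baseline_scale Overall scale of the random smooth fluorescence
#'   baseline (5th-order polynomial with positive offset); 0 disables it.
#' @param noise_sd Additive Gaussian noise SD (intensity units); spectra are
#'   clipped at zero after noise.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = default_group_means(),
                          between_sd = 0.05,
                          within_sd = 0.08,
                          spectra_per_mouse = 235,
                          spectra_per_mouse_sd = 25,
                          baseline_scale = 1,
                          noise_sd = 0.01,
                          seed = 1L) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "n_mice") %in% names(groups)))
  if (any(groups$n_mice < 1)) stop("every group needs n_mice >= 1")
  ab_cols <- setdiff(names(groups), c("group", "n_mice"))
  if (any(as.matrix(groups[, ab_cols]) < 0)) {
    stop("mean abundances must be non-negative")
  }
  if (between_sd < 0 || within_sd < 0 || noise_sd < 0 ||
      spectra_per_mouse_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (spectra_per_mouse <= 0) stop("spectra_per_mouse mean must be positive")
  structure(
    list(
      groups = groups,
      components = ab_cols,
      between_sd = between_sd,
      within_sd = within_sd,
      spectra_per_mouse = spectra_per_mouse,
      spectra_per_mouse_sd = spectra_per_mouse_sd,
      baseline_scale = baseline_scale,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' Default group mean abundances for the four-group cohort
#'
#' Lipid-like abundance rises and collagen-like falls with metastatic
#' potential; the formalin-like contaminant and the two mixed components
#' are phenotype-neutral. The within/between-mouse spreads in
#' [cohort_design()] make mouse-level classification challenging but
#' solvable.
#'
#' @return data.frame with columns `group`, `n_mice` and one column per
#'   default library component.
#' @export
default_group_means <- function() {
  data.frame(
    group = c("67NR", "FARN", "4T07", "4T1"),
    n_mice = c(8L, 6L, 5L, 8L),
    lipid_like = c(0.30, 0.48, 0.60, 0.80),
    collagen_like = c(0.85, 0.68, 0.55, 0.38),
    formalin_like = c(0.30, 0.30, 0.30, 0.30),
    mixed_1 = c(0.50, 0.50, 0.50, 0.50),
    mixed_2 = c(0.40, 0.40, 0.40, 0.40),
    stringsAsFactors = FALSE
  )
}

# Smooth random fluorescence baseline: 5th-order polynomial on x in [-1, 1]
# with a positive offset, shifted to stay non-negative.
random_baseline <- function(grid, scale) {
  if (scale <= 0) return(numeric(length(grid)))
  x <- seq(-1, 1, length.out = length(grid))
  coef_sd <- c(0, 0.4, 0.2, 0.1, 0.05, 0.025) * scale
  coefs <- stats::rnorm(6, mean = 0, sd = pmax(coef_sd, 1e-12))
  coefs[1] <- stats::runif(1, 0.5, 1.5) * scale
  b <- drop(outer(x, 0:5, `^`) %*% coefs)
  b - min(b, 0) # keep the background non-negative
}

simulate_groups <- function(design, library, groups, cohort_name, seed,
                            shift_record = NULL) {
  comp <- design$components
  if (!setequal(comp, library$names)) {
    stop("design abundance columns must match the library components")
  }
  profiles <- library$profiles[comp, , drop = FALSE]
  grid <- library$wavenumbers
  nchan <- length(grid)

  withr::with_seed(seed, {
    spectra <- list()
    meta <- list()
    truth <- list()
    mouse_truth <- list()
    for (gi in seq_len(nrow(groups))) {
      g <- groups$group[gi]
      n_mice <- groups$n_mice[gi]
      g_mean <- as.numeric(groups[gi, comp])
      for (m in seq_len(n_mice)) {
        mouse_id <- sprintf("%s_m%02d", g, m)
        mouse_mean <- pmax(
          g_mean + stats::rnorm(length(comp), 0, design$between_sd), 0
        )
        n_spec <- max(1L, as.integer(round(
          stats::rnorm(1, design$spectra_per_mouse,
                       design$spectra_per_mouse_sd)
        )))
        ab <- matrix(
          pmax(rep(mouse_mean, each = n_spec) +
                 stats::rnorm(n_spec * length(comp), 0, design$within_sd), 0),
          nrow = n_spec
        )
        clean <- ab %*% profiles
        out <- clean
        if (design$baseline_scale > 0) {
          for (s in seq_len(n_spec)) {
            out[s, ] <- out[s, ] +
              random_baseline(grid, design$baseline_scale)
          }
        }
        if (design$noise_sd > 0) {
          out <- out + matrix(stats::rnorm(n_spec * nchan, 0, design$noise_sd),
                              nrow = n_spec)
        }
        out <- pmax(out, 0)
        ids <- sprintf("%s_s%04d", mouse_id, seq_len(n_spec))
        spectra[[length(spectra) + 1L]] <- out
        meta[[length(meta) + 1L]] <- data.frame(
          spectrum_id = ids, mouse_id = mouse_id, group = g,
          cohort = cohort_name, stringsAsFactors = FALSE
        )
        tr <- as.data.frame(ab)
        names(tr) <- comp
        truth[[length(truth) + 1L]] <- cbind(
          data.frame(spectrum_id = ids, mouse_id = mouse_id, group = g,
                     stringsAsFactors = FALSE), tr
        )
        mt <- as.data.frame(as.list(mouse_mean))
        names(mt) <- comp
        mouse_truth[[length(mouse_truth) + 1L]] <- cbind(
          data.frame(mouse_id = mouse_id, group = g,
                     stringsAsFactors = FALSE), mt
        )
      }
    }
    dataset <- spectra_dataset(
      grid, do.call(rbind, spectra), do.call(rbind, meta),
      provenance = sprintf("simulate(seed=%d)", seed)
    )
    ground_truth <- structure(
      list(
        spectrum_abundances = do.call(rbind, truth),
        mouse_abundances = do.call(rbind, mouse_truth),
        shift = shift_record
      ),
      class = "ground_truth"
    )
    list(dataset = dataset, truth = ground_truth)
  })
}

#' Simulate a synthetic Raman cohort with known ground truth
#'
#' Each spectrum is a non-negative linear combination of the library
#' profiles plus a smooth random polynomial baseline and additive Gaussian
#' noise, clipped at zero. Mouse mean abundances are drawn once per mouse;
#' per-spectrum abundances jitter around them. Fully reproducible from
#' `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param library A [build_component_library()] result sharing the grid.
#' @return List with `dataset` (a [spectra_dataset()]) and `truth` (a
#'   `ground_truth` object holding per-spectrum and per-mouse abundances).
#' @export
simulate_cohort <- function(design, library = build_component_library()) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(library, "component_library"))
  simulate_groups(design, library, design$groups, cohort_name = "primary",
                  seed = design$seed)
}

#' Default design for the gene-silenced external cohorts
#'
#' Knockout/knockdown analogs (TWIST-KO n = 8, FOXC2-KD n = 7, CXCR3-KD
#' n = 6) shift lipid-like abundance down and collagen-like up relative to
#' the fully metastatic reference group, emulating the loss of metastatic
#' potential after silencing; vector controls (FOXC2-VC n = 7, CXCR3-VC
#' n = 6) carry zero shift.
#'
#' @param reference_group Name of the reference group in the primary design.
#' @return data.frame with columns `group`, `n_mice`, `lipid_shift`,
#'   `collagen_shift` and `reference`.
#' @export
default_external_shifts <- function(reference_group = "4T1") {
  data.frame(
    group = c("TWIST-KO", "FOXC2-KD", "FOXC2-VC", "CXCR3-KD", "CXCR3-VC"),
    n_mice = c(8L, 7L, 7L, 6L, 6L),
    lipid_shift = c(-0.35, -0.25, 0, -0.25, 0),
    collagen_shift = c(0.30, 0.20, 0, 0.20, 0),
    reference = reference_group,
    stringsAsFactors = FALSE
  )
}

#' Simulate external (gene-silenced analog) cohorts
#'
#' Group mean abundances are taken from a named reference group of the
#' primary design and shifted per external group (lipid-like down,
#' collagen-like up for knockdown analogs; zero shift for vector controls).
#' Generation then proceeds exactly as in [simulate_cohort()].
#'
#' @param shifts data.frame as returned by [default_external_shifts()].
#' @param library Component library shared with the reference design.
#' @param reference A [cohort_design()] containing the reference group.
#' @param seed Integer seed for the external cohort.
#' @return List with `dataset` and `truth`; `truth$shift` records the
#'   applied shifts.
#' @export
simulate_external_cohort <- function(shifts = default_external_shifts(),
                                     library = build_component_library(),
                                     reference = cohort_design(),
                                     seed = reference$seed + 1L) {
  stopifnot(inherits(reference, "cohort_design"))
  comp <- reference$components
  groups <- NULL
  for (i in seq_len(nrow(shifts))) {
    ref_row <- reference$groups[reference$groups$group == shifts$reference[i], ]
    if (nrow(ref_row) == 0) {
      stop("unknown reference group: ", shifts$reference[i])
    }
    means <- as.numeric(ref_row[1, comp])
    names(means) <- comp
    means["lipid_like"] <- max(0, means["lipid_like"] + shifts$lipid_shift[i])
    means["collagen_like"] <- max(0, means["collagen_like"] +
                                    shifts$collagen_shift[i])
    row <- cbind(
      data.frame(group = shifts$group[i], n_mice = shifts$n_mice[i],
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(means))
    )
    groups <- rbind(groups, row)
  }
  design <- reference
  design$groups <- groups
  simulate_groups(design, library, groups, cohort_name = "external",
                  seed = as.integer(seed), shift_record = shifts)
}
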