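# Shared fixtures, built once per test run and cached. Cohorts are scaled
# down (60 spectra per mouse instead of the study's ~235) to keep the suite
# fast; group structure, mouse counts and difficulty match the default
# design.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_library <- function() {
  fixture("library", function() build_component_library())
}

# seeded scaled 27-mouse cohort (raw + preprocessed + multiclass labels)
cohort_small <- function() {
  fixture("cohort_small", function() {
    design <- cohort_design(spectra_per_mouse = 60, spectra_per_mouse_sd = 6,
                            seed = 42)
    sim <- simulate_cohort(design, default_library())
    clean <- preprocess_dataset(sim$dataset)
    list(
      design = design,
      raw = sim$dataset,
      truth = sim$truth,
      clean = clean,
      labeled = make_labels(clean, label_scheme("multiclass"))
    )
  })
}

# matching gene-silenced analog cohorts
external_small <- function() {
  fixture("external_small", function() {
    co <- cohort_small()
    ext <- simulate_external_cohort(default_external_shifts(),
                                    default_library(), co$design, seed = 43)
    list(raw = ext$dataset, truth = ext$truth,
         clean = preprocess_dataset(ext$dataset))
  })
}

# single-spectrum dataset helper for the per-spectrum preprocessing ops
one_spectrum <- function(wavenumbers, intensities, id = "s1") {
  spectra_dataset(wavenumbers, matrix(intensities, nrow = 1),
                  data.frame(spectrum_id = id, mouse_id = "m1", group = "g1"))
}

# tiny two-class cohort for classifier unit tests
tiny_two_class <- function(seed = 5, noise_sd = 0.01) {
  fixture(sprintf("tiny2_%d_%g", seed, noise_sd), function() {
    lib <- default_library()
    groups <- data.frame(
      group = c("neg", "pos"), n_mice = c(3L, 3L),
      lipid_like = c(0.3, 0.8), collagen_like = c(0.8, 0.3),
      formalin_like = 0.3, mixed_1 = 0.5, mixed_2 = 0.4
    )
    design <- cohort_design(groups = groups, spectra_per_mouse = 12,
                            spectra_per_mouse_sd = 0, baseline_scale = 0,
                            noise_sd = noise_sd, seed = seed)
    sim <- simulate_cohort(design, lib)
    make_labels(sim$dataset,
                label_scheme("custom", map = c(neg = "neg", pos = "pos")))
  })
}
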