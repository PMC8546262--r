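# Shared fixtures, built lazily and memoised across test files. Two tiers:
# "tiny" (320 elements/surface) for unit tests of the machinery, and "study"
# (1,280 elements/surface, the coarse study meshes) for the end-to-end and
# acceptance checks.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

tiny_head <- function() fixture("tiny_head",
  make_sphere_head(elements_per_surface = 320))

tiny_layout <- function() fixture("tiny_layout",
  place_electrodes_10_5(tiny_head()$surfaces[[1]]))

tiny_lesioned <- function() fixture("tiny_lesioned",
  add_spherical_lesion(tiny_head(),
                       lesion_spec(default_lesion_center(), 23, 1.23),
                       elements = 320))

tiny_pair <- function() fixture("tiny_pair", {
  pt <- find_optimal_pair(tiny_lesioned(), tiny_head(), tiny_layout(),
                          refine = "none")
  opt <- attr(pt, "optimal")
  c(opt$anode, opt$cathode)
})

tiny_cache <- function() fixture("tiny_cache",
  lesion_forward_cache(tiny_lesioned(), tiny_pair(), tiny_layout()))

study_head <- function() fixture("study_head",
  make_sphere_head(elements_per_surface = 1280))

study_layout <- function() fixture("study_layout",
  place_electrodes_10_5(study_head()$surfaces[[1]]))

study_lesioned <- function() fixture("study_lesioned",
  add_spherical_lesion(study_head(),
                       lesion_spec(default_lesion_center(), 23, 1.23),
                       elements = 1280))

study_pair <- function() fixture("study_pair", {
  pt <- find_optimal_pair(study_lesioned(), study_head(), study_layout())
  opt <- attr(pt, "optimal")
  c(opt$anode, opt$cathode)
})

study_cache <- function() fixture("study_cache",
  lesion_forward_cache(study_lesioned(), study_pair(), study_layout()))

# antipodal +-x stimulation pair at 3 mm depth in the default sphere head
antipodal_sources <- function(current = 1e-4) {
  source_config(rbind(c(89, 0, 0), c(-89, 0, 0)), c(current, -current))
}

# four-shell and homogeneous layered-sphere oracles for the default radii
four_shell_oracle <- function(n_max = 3000) {
  layered_sphere_model(c(0.092, 0.086, 0.080, 0.078),
                       c(0.414, 0.016, 1.71, 0.37), n_max = n_max)
}
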