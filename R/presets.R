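## Versioned geometric-cutoff presets.  The "paper-profile" preset freezes
## the conventional MD criteria used for every reported occupancy so results
## are reproducible; individual values can be overridden per analysis but the
## preset itself is immutable.

.PAPER_PROFILE <- list(
  name = "paper-profile",
  version = "1.0",
  hbond_dist = 3.5,          # donor-acceptor heavy-atom distance, Angstrom
  hbond_angle = 120,         # D-H...A angle at the hydrogen, degrees
  salt_bridge_dist = 4.0,    # minimum N-O distance, Angstrom
  hydrophobic_dist = 4.5,    # minimum heavy-atom distance, Angstrom
  pi_centroid_dist = 5.5,    # ring centroid separation, Angstrom
  pi_parallel_angle = 30,    # interplanar angle upper bound, parallel
  pi_tshape_range = c(60, 90), # interplanar angle window, T-shaped
  na_shell_cutoff = 3.2,     # Na+ first-shell water-oxygen cutoff, Angstrom
  na_contact_dist = 3.2,     # Na+ to Asp2.50 carboxylate O, Angstrom
  lid_centroid_dist = 6.0,   # Phe6.44 ring centroid to Na+, Angstrom
  water_edge_dist = 3.5,     # water O-O hydrogen-bond graph edge, Angstrom
  water_attach_dist = 4.0,   # water to vestibule / sink attachment, Angstrom
  dtm_threshold = 10.5,      # TM3-TM6 gap midpoint between 9 and 12, Angstrom
  dil_threshold = 10.0,      # ionic-lock midpoint between 4 and 16, Angstrom
  rmsd_threshold = 2.0,      # agonist-compatible pose bound, Angstrom
  ma_window = 20             # moving-average window, frames
)

#' Named geometric-parameter presets
#'
#' `presets()` lists the available presets; `preset(name, overrides)` returns
#' one, optionally with individual cutoffs overridden (overrides are recorded
#' under `$overridden`).
#'
#' @param name preset name; currently `"paper-profile"`.
#' @param overrides named list of cutoff overrides.
#' @return list of geometric parameters.
#' @export
preset <- function(name = "paper-profile", overrides = list()) {
  base <- switch(name,
    "paper-profile" = .PAPER_PROFILE,
    .err(paste("unknown preset:", name), "config_error"))
  bad <- setdiff(names(overrides), names(base))
  if (length(bad)) .err(paste("unknown preset parameters:",
                              paste(bad, collapse = ", ")), "config_error")
  out <- utils::modifyList(base, overrides)
  out$overridden <- names(overrides)
  out
}

#' @rdname preset
#' @export
presets <- function() "paper-profile"
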