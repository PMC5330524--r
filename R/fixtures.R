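# Pinned fixture geometries.  The production-analog fixtures (N2, cyanide,
# water) carry coordinates produced by this package's own
# optimize_geometry() runs at the CISD level in the package's split-valence
# basis; the provenance (method/basis, residual gradient) is recorded in the
# comment and re-derivable with the code in the methods vignette.  Desk-
# scale fixtures (H2 and friends) are simple symmetric geometries used by
# the fast tests.

FIXTURES <- list(
  H2_test = function() molecule(
    c(1L, 1L), rbind(c(0, 0, -0.7), c(0, 0, 0.7)),
    comment = "H2 desk fixture, r = 1.4 bohr (symmetric, pinned)"),
  H2 = function() molecule(
    c(1L, 1L), rbind(c(0, 0, -0.7), c(0, 0, 0.7)),
    comment = "H2 desk fixture, r = 1.4 bohr (symmetric, pinned)"),
  He = function() molecule(
    2L, matrix(c(0, 0, 0), 1), comment = "helium atom"),
  N2 = function() molecule(
    c(7L, 7L), rbind(c(0, 0, -1.0441005), c(0, 0, 1.0441005)),
    comment = "N2, self-optimized CISD/6-31gdp, r = 2.088201 bohr (grid scan + parabolic polish)"),
  `CN-` = function() molecule(
    c(6L, 7L), rbind(c(0, 0, -1.1167345), c(0, 0, 1.1167345)),
    charge = -1L,
    comment = "cyanide anion, self-optimized CISD/6-31gdp, r = 2.233469 bohr (grid scan + parabolic polish)"),
  water = function() molecule(
    c(8L, 1L, 1L),
    rbind(c(0, 0, 0),
          c(0, 1.4289240, -1.1096425),
          c(0, -1.4289240, -1.1096425)),
    comment = "water, self-optimized CISD/6-31gdp, C2v Newton on (r_OH, angle): r = 1.809179 bohr, HOH = 104.33 deg, |grad| ~ 1e-6")
)

#' Pinned fixture geometries
#'
#' Returns one of the package's pinned molecular geometries.  Production-
#' analog fixtures (`"N2"`, `"CN-"`, `"water"`) are this package's own
#' CISD-optimized structures in its split-valence basis; desk-scale
#' fixtures (`"H2_test"`, `"He"`) are simple pinned geometries for fast
#' tests.  Coordinates are in bohr; provenance is in the `comment` field.
#'
#' @param name fixture name; see `names(xcwfit:::FIXTURES)`.
#' @return An [molecule()].
#' @export
fixture_geometry <- function(name) {
  f <- FIXTURES[[name]]
  if (is.null(f)) {
    stop("unknown fixture \"", name, "\"; available: ",
         paste(names(FIXTURES), collapse = ", "))
  }
  f()
}

# named bonds (atom index pairs) for the TI tables of each fixture
fixture_bonds <- function(name) {
  switch(name,
         N2 = list(`N-N` = c(1L, 2L)),
         `CN-` = list(`C-N` = c(1L, 2L)),
         water = list(`O-H` = c(1L, 2L)),
         H2 = ,
         H2_test = list(`H-H` = c(1L, 2L)),
         stop("no bond table for fixture ", name))
}
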