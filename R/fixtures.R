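#' Load a packaged fixture
#'
#' The package ships three versioned, checksummed text fixtures:
#' \describe{
#'   \item{`grid1471`}{A 1471-site neuron grid on a 1-cm lattice filling a
#'     brain-shaped ellipsoid in a Talairach-like coordinate frame (mm).
#'     The site count matches the atlas-derived grid used by 3D SNN
#'     reservoirs; the coordinates themselves are a synthetic lattice, not
#'     the atlas (see the file name).}
#'   \item{`montage62`}{The 62-channel 10-20/10-10 EEG montage with 3D
#'     coordinates obtained by spherical projection onto the same ellipsoid.}
#'   \item{`regions_fig5`}{The mapping of the 62 channels to five anatomical
#'     sites (frontal, frontocentral, temporal, centroparietal,
#'     occipitoparietal) by hemisphere; the 8 midline channels carry
#'     hemisphere `"midline"` and no site.}
#' }
#' Checksums in `fixtures_manifest.json` are verified at load.
#'
#' @param name One of `"grid1471"`, `"montage62"`, `"regions_fig5"`.
#' @return For `grid1471`, a numeric matrix with columns x, y, z; for
#'   `montage62`, a data.frame with `channel`, `x`, `y`, `z`; for
#'   `regions_fig5`, a data.frame with `channel`, `site`, `hemisphere`.
#' @examples
#' nrow(load_fixture("grid1471"))   # 1471
#' head(load_fixture("montage62"))
#' @export
load_fixture <- function(name = c("grid1471", "montage62", "regions_fig5")) {
  name <- match.arg(name)
  dir <- system.file("extdata", package = "snnerp")
  manifest <- jsonlite::read_json(file.path(dir, "fixtures_manifest.json"))
  path <- file.path(dir, manifest$files[[name]])
  got <- unname(tools::md5sum(path))
  if (!identical(got, manifest$md5[[name]])) {
    stop_snnerp(sprintf("fixture '%s' failed its checksum (%s != %s)",
                        name, got, manifest$md5[[name]]),
                "snnerp_integrity_error")
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  switch(name,
    grid1471 = as.matrix(x),
    montage62 = x,
    regions_fig5 = {
      x$site[!is.na(x$site) & x$site == ""] <- NA
      x
    })
}

#' The 62 montage channel labels in recording order
#' @return Character vector of length 62.
#' @export
montage_channels <- function() {
  load_fixture("montage62")$channel
}
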