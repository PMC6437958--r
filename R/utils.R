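#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' maupsi: multiscale zonation ensembles and simulation intervals
#'
#' See the methods vignette
#' (`vignette("simulation-intervals", package = "maupsi")`) for the model,
#' the zone-design algorithm, and the simulation-interval construction.
#'
#' @keywords internal
"_PACKAGE"
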