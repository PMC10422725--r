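#' Maxillary arch width from paired landmarks
#'
#' Skeletal palatal width (PW) and dento-alveolar width (DAW) at a tooth
#' level (P1, P2, M1) are Euclidean distances between the left and right
#' landmark of the pair. Landmark anatomy is declared by the naming
#' convention of the landmark file, not hard-coded: the point names are
#' `<kind>_<level>_<side>` with kind `PW`/`DAW`, level `P1`/`P2`/`M1`,
#' side `L`/`R` (e.g. `PW_M1_L`).
#'
#' @param landmarks named list of 3D points for one patient and timepoint.
#' @param level `"P1"`, `"P2"` or `"M1"`.
#' @param kind `"PW"` (skeletal) or `"DAW"` (dento-alveolar).
#' @return width in mm.
#' @export
arch_width <- function(landmarks, level = c("P1", "P2", "M1"),
                       kind = c("PW", "DAW")) {
  level <- match.arg(level); kind <- match.arg(kind)
  ln <- paste(kind, level, "L", sep = "_")
  rn <- paste(kind, level, "R", sep = "_")
  if (!all(c(ln, rn) %in% names(landmarks)))
    stop("missing arch landmark pair ", ln, " / ", rn)
  sqrt(sum((as.numeric(landmarks[[ln]]) - as.numeric(landmarks[[rn]]))^2))
}

#' Expansion change between timepoints
#'
#' PWE/DAE are the T0 - T1 width differences per level: an expansion
#' (wider arch at T1) yields negative values by this sign convention.
#'
#' @param t0_landmarks,t1_landmarks arch landmark lists per timepoint.
#' @param levels levels to compute.
#' @return data.frame with columns `level`, `pwe`, `dae` (mm).
#' @export
expansion_change <- function(t0_landmarks, t1_landmarks,
                             levels = c("P1", "P2", "M1")) {
  rows <- lapply(levels, function(lv) {
    data.frame(level = lv,
               pwe = arch_width(t0_landmarks, lv, "PW") -
                     arch_width(t1_landmarks, lv, "PW"),
               dae = arch_width(t0_landmarks, lv, "DAW") -
                     arch_width(t1_landmarks, lv, "DAW"))
  })
  do.call(rbind, rows)
}
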