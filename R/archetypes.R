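#' Trajectory archetype shapes
#'
#' Deterministic z-score expectation for a case protein as a function of
#' lead time (years from blood draw to diagnosis). Four archetypes encode
#' the qualitative trajectory families seen in pre-diagnostic proteomes:
#'
#' 1. early-abnormal exponential rise peaking at diagnosis:
#'    `z(t) = 3 * exp(-b t)` with `b` set so `z(15) = 1`;
#' 2. persistently elevated, stable: `z(t) = 0.8`;
#' 3. sharp rise to abnormal levels close to diagnosis then plateau:
#'    logistic step centred 3 years pre-diagnosis, rising 0 to 0.9;
#' 4. early peak then return to normal: Gaussian bump centred 15 years
#'    pre-diagnosis, height 0.9, SD 4 years.
#'
#' Magnitudes are chosen so that the abnormality threshold 0.45 z-units
#' separates the regimes: archetype 1 is abnormal over the whole window,
#' archetype 4 is abnormal only at long lead times.
#'
#' @param archetype Integer in 1..4.
#' @param lead_time Numeric vector of lead times in years, within \[0, 15\].
#' @return Numeric vector of z-unit expectations.
#' @examples
#' archetype_shape(1, c(0, 15))   # 3.0 at diagnosis, 1.0 at 15 years
#' archetype_shape(4, c(0, 15))   # near 0 at diagnosis, 0.9 at 15 years
#' @export
archetype_shape <- function(archetype, lead_time) {
  if (length(archetype) != 1L || !archetype %in% 1:4) {
    stop("unknown archetype id: ", paste(archetype, collapse = ","),
         call. = FALSE)
  }
  if (any(lead_time < 0 | lead_time > 15)) {
    stop("lead_time must lie in [0, 15] years", call. = FALSE)
  }
  switch(archetype,
    # 1: z(15) = 1, z(0) = 3, monotone increasing toward diagnosis
    3 * exp(-(log(3) / 15) * lead_time),
    # 2: stable elevation
    rep(0.8, length(lead_time)),
    # 3: logistic step centred 3 y pre-diagnosis, scale 0.75 y
    0.9 / (1 + exp((lead_time - 3) / 0.75)),
    # 4: Gaussian bump centred 15 y, height 0.9, SD 4 y
    0.9 * exp(-(lead_time - 15)^2 / (2 * 4^2))
  )
}
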