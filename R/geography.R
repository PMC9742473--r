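#' Generate the state / CRD / county hierarchy
#'
#' Counties get 5-character zero-padded GEOIDs (2-digit state code + 3-digit
#' county number), a CRD label within their state, and a cropland ratio drawn
#' from a Beta distribution parameterised by mean and concentration.
#'
#' @param config a [scenario_config()] object.
#' @return data.table with columns `geoid`, `state`, `crd`, `cropland_ratio`.
#' @export
build_geography <- function(config) {
  stopifnot(inherits(config, "yc_scenario"))
  ns <- config$n_states; nc <- config$crds_per_state
  nk <- config$counties_per_crd
  with_seed(derive_seed(config$seed, "geography"), {
    g <- data.table::CJ(state_i = seq_len(ns), crd_i = seq_len(nc),
                        cty_i = seq_len(nk), sorted = TRUE)
    g[, state := config$state_codes[state_i]]
    g[, crd := sprintf("%s-%02d", state, crd_i)]
    g[, geoid := sprintf("%02d%03d", state_i, (crd_i - 1L) * nk + cty_i)]
    m <- config$cropland$mean; k <- config$cropland$conc
    g[, cropland_ratio := rbeta(.N, m * k, (1 - m) * k)]
    out <- g[, .(geoid, state, crd, cropland_ratio)]
    data.table::setkey(out, geoid)
    out[]
  })
}
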