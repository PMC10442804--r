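#' Read a pipeline configuration from YAML
#'
#' The configuration may carry any of: `roi_aliases` (raw name ->
#' canonical ROI), `paired_organs` (list of `family`/`left`/`right`
#' entries), and `feature_specs` (per symptom: `organs`, `vx_lo`, `vx_hi`,
#' optional `vx_step`, `include_max`, `ntcp_organs`). Missing blocks fall
#' back to the shipped defaults.
#'
#' @param path YAML file path.
#' @return a list with `roi_aliases`, `paired_organs`, `feature_specs`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  aliases <- NULL
  if (!is.null(cfg$roi_aliases))
    aliases <- unlist(cfg$roi_aliases)
  pairs <- default_paired_organs()
  if (!is.null(cfg$paired_organs)) {
    pairs <- do.call(rbind, lapply(cfg$paired_organs, function(p)
      data.frame(family = p$family, left = p$left, right = p$right,
                 stringsAsFactors = FALSE)))
  }
  specs <- default_feature_specs()
  if (!is.null(cfg$feature_specs)) {
    for (sym in names(cfg$feature_specs)) {
      fs <- cfg$feature_specs[[sym]]
      specs[[sym]] <- feature_spec(
        sym, organs = unlist(fs$organs),
        vx_lo = fs$vx_lo, vx_hi = fs$vx_hi,
        vx_step = fs$vx_step %||% 5,
        include_max = isTRUE(fs$include_max),
        ntcp_organs = unlist(fs$ntcp_organs) %||% unlist(fs$organs))
    }
  }
  list(roi_aliases = aliases, paired_organs = pairs,
       feature_specs = specs)
}

#' Write a mined rule set as YAML
#'
#' One entry per rule (feature, full-precision threshold in Gy, a rounded
#' display threshold, direction) plus the quality metrics.
#'
#' @param rs a [beam_search_rules()] result.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_rules_yaml <- function(rs, path) {
  stopifnot(inherits(rs, "rule_set"))
  out <- list(
    rules = lapply(seq_len(nrow(rs$rules)), function(i) list(
      feature = rs$rules$feature[i],
      threshold_gy = rs$rules$threshold[i],
      threshold_display = round(rs$rules$threshold[i]),
      direction = rs$rules$direction[i])),
    quality = list(precision = rs$precision, recall = rs$recall,
                   mi_bits = rs$mi_bits, n_shd = rs$n_shd,
                   n_hd = rs$n_hd))
  yaml::write_yaml(out, path)
  invisible(path)
}
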