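#' @importFrom rlang %||% abort warn .data
#' @import tibble
#' @importFrom dplyr filter mutate select arrange left_join group_by summarise
#'   ungroup bind_rows bind_cols pull rename n distinct across everything
#'   if_else row_number
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap keep
#' @importFrom stats median optimize setNames runif
#' @importFrom utils write.table read.table modifyList
NULL

# strip a bracketed compartment suffix: "atp[m]" -> "atp"
met_base_id <- function(id) sub("\\[[^]]*\\]$", "", id)

# compartment code from a bracketed suffix: "atp[m]" -> "m" ("" if none)
met_compartment <- function(id) {
  out <- rep("", length(id))
  hit <- grepl("\\[[^]]*\\]$", id)
  out[hit] <- sub("^.*\\[([^]]*)\\]$", "\\1", id[hit])
  out
}

finite_or <- function(x, default) ifelse(is.finite(x), x, default)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
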