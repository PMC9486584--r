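# shared internal helpers

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# canonical node key: one string per (layer, feature) pair
node_key <- function(layer, feature) paste(layer, feature, sep = "::")

split_node_key <- function(key) {
  parts <- strsplit(key, "::", fixed = TRUE)
  tibble(
    layer = vapply(parts, `[[`, character(1), 1L),
    feature = vapply(parts, function(p) paste(p[-1L], collapse = "::"), character(1))
  )
}

# undirected edge identity, independent of endpoint listing order
edge_pair_key <- function(key_a, key_b) {
  paste(pmin(key_a, key_b), pmax(key_a, key_b), sep = "\r")
}

`%not_in%` <- function(x, table) !(x %in% table)
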