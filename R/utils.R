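#' Derive a child seed from a root seed
#'
#' All stochastic stages derive their own seed from the scenario root seed so
#' that each stage is individually reproducible regardless of call order.
#' Results stay below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param salt integer stage identifier.
#' @return an integer seed.
#' @export
mix_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 1009) %% 2147483647L)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601 timestamp helpers (all times UTC).
format_iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    # fall back to a space separator
    out[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  out
}

#' Export a weighted network as GraphML
#'
#' Writes an undirected weighted graph (e.g. an SRI association matrix) in
#' GraphML, with node attributes taken from `node_attrs`.
#'
#' @param mat symmetric numeric matrix with dimnames; zero entries are
#'   non-edges.
#' @param path output file path.
#' @param node_attrs optional data.frame keyed by node id (first column) with
#'   additional character attributes.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(mat, path, node_attrs = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  ids <- rownames(mat)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"w\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>"
  )
  attr_keys <- character(0)
  if (!is.null(node_attrs)) {
    attr_keys <- setdiff(names(node_attrs), names(node_attrs)[1])
    for (k in attr_keys) {
      lines <- c(lines, sprintf(
        "  <key id=\"%s\" for=\"node\" attr.name=\"%s\" attr.type=\"string\"/>",
        esc(k), esc(k)))
    }
  }
  lines <- c(lines, "  <graph edgedefault=\"undirected\">")
  for (v in ids) {
    if (length(attr_keys)) {
      row <- node_attrs[match(v, node_attrs[[1]]), , drop = FALSE]
      data <- vapply(attr_keys, function(k) sprintf(
        "<data key=\"%s\">%s</data>", esc(k), esc(as.character(row[[k]]))),
        character(1))
      lines <- c(lines, sprintf("    <node id=\"%s\">%s</node>",
                                esc(v), paste(data, collapse = "")))
    } else {
      lines <- c(lines, sprintf("    <node id=\"%s\"/>", esc(v)))
    }
  }
  n <- length(ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (mat[i, j] > 0) {
          lines <- c(lines, sprintf(
            "    <edge source=\"%s\" target=\"%s\"><data key=\"w\">%.10g</data></edge>",
            esc(ids[i]), esc(ids[j]), mat[i, j]))
        }
      }
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
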