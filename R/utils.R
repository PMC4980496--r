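# Internal helpers shared across the package.

# Locale-independent sort (C collation) so every ordering in the package is
# reproducible across platforms.
sort_c <- function(x) sort(unique(as.character(x)), method = "radix")

sort_keep_dup <- function(x) sort(as.character(x), method = "radix")

order_c <- function(x) order(x, method = "radix")

#' @noRd
stop_dcnet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dcnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Taxon labels must survive Newick serialization and the composite-taxon
# naming scheme, so the usual reserved characters are rejected.
check_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- !nzchar(labels) | grepl("[,()#;:\\s]", labels, perl = TRUE)
  if (any(bad)) {
    stop_dcnet(
      sprintf("invalid taxon label(s): %s", paste(dQuote(labels[bad]), collapse = ", ")),
      "dcnet_invalid_label"
    )
  }
  labels
}

# Encoding of a single cluster / of a cluster list, used for deterministic
# ordering and deduplication.
cluster_code <- function(members) paste(sort_keep_dup(members), collapse = ",")

clusters_codes <- function(clusters) vapply(clusters, cluster_code, character(1))

# Name for the composite taxon replacing a collapsed block of original taxa.
composite_label <- function(block) paste(sort_c(block), collapse = "+")

vset_equal <- function(a, b) length(a) == length(b) && all(a %in% b)
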