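#' Construct a feature table
#'
#' One row of named feature values per clip, with per-clip labels and
#' identifiers. All rows must share the same feature names in the same
#' order.
#'
#' @param values numeric matrix (clips x features) with column names.
#' @param labels character vector of class labels per clip.
#' @param clip_ids character vector of clip identifiers.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(values, labels, clip_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("feature columns must be named", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("feature names must be unique", call. = FALSE)
  if (nrow(values) != length(labels)) stop("one label per row required", call. = FALSE)
  if (any(!is.finite(values))) stop("all feature values must be finite", call. = FALSE)
  if (is.null(clip_ids)) clip_ids <- paste0("clip", seq_len(nrow(values)))
  structure(list(values = values, labels = as.character(labels),
                 clip_ids = as.character(clip_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d clips x %d features, classes: %s>\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Extract one feature domain for a list of clips
#'
#' Dispatches to the per-domain extractors and stacks the resulting
#' vectors into a [feature_table]. Column names are stable across calls;
#' extraction is deterministic.
#'
#' @param clips list of [audio_clip] objects.
#' @param domain one of "time", "freq", "dwt", "sparse", "eigen", "ceps".
#' @param frame_ms,hop_ms framing parameters in milliseconds.
#' @return a [feature_table].
#' @export
extract_domain <- function(clips, domain, frame_ms = 25, hop_ms = 10) {
  if (length(clips) == 0L) stop("empty clip list", call. = FALSE)
  domain <- match.arg(domain, c("time", "freq", "dwt", "sparse", "eigen", "ceps"))
  rows <- lapply(clips, function(cl) {
    switch(domain,
      time = time_domain_features(cl, frame_raw(cl, frame_ms, hop_ms)),
      freq = {
        fw <- frame_signal(cl, frame_ms, hop_ms, "hamming")
        fr <- frame_raw(cl, 40, hop_ms)
        c(spectral_shape_features(fw), ltas_features(fw),
          tonality_features(cl, fr), autoregressive_features(fw))
      },
      dwt = dwt_features(cl),
      sparse = sparse_features(cl),
      eigen = eigen_features(frame_signal(cl, frame_ms, hop_ms, "hamming")),
      ceps = cepstral_features(frame_signal(cl, frame_ms, hop_ms, "hamming")))
  })
  nm <- names(rows[[1]])
  vals <- do.call(rbind, lapply(rows, function(r) {
    if (!identical(names(r), nm)) stop("inconsistent feature names across clips")
    r
  }))
  colnames(vals) <- nm
  feature_table(vals,
                labels = vapply(clips, function(cl) cl$label, character(1)),
                clip_ids = vapply(clips, function(cl) cl$clip_id, character(1)))
}

#' Extract and column-bind several feature domains
#'
#' @param clips list of [audio_clip] objects.
#' @param domains character vector of domain tags.
#' @return a [feature_table] with the domains' columns concatenated.
#' @export
extract_domains <- function(clips, domains) {
  tabs <- lapply(domains, function(d) extract_domain(clips, d))
  vals <- do.call(cbind, lapply(tabs, function(t) t$values))
  feature_table(vals, tabs[[1]]$labels, tabs[[1]]$clip_ids)
}

#' Write / read a feature table as CSV
#'
#' Columns: clip_id, label, then one column per feature.
#'
#' @param table a [feature_table].
#' @param path CSV file path.
#' @return `path` invisibly (write) or a [feature_table] (read).
#' @export
write_feature_csv <- function(table, path) {
  df <- data.frame(clip_id = table$clip_ids, label = table$labels,
                   table$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feature_table(as.matrix(df[, -(1:2), drop = FALSE]),
                labels = df$label, clip_ids = df$clip_id)
}

# subset the feature columns of a table by a logical/integer mask
mask_table <- function(table, bits) {
  sel <- if (is.logical(bits)) which(bits) else which(bits > 0)
  feature_table(table$values[, sel, drop = FALSE], table$labels, table$clip_ids)
}

# row subset
subset_table <- function(table, idx) {
  feature_table(table$values[idx, , drop = FALSE],
                table$labels[idx], table$clip_ids[idx])
}
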