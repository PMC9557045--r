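#' Load implant size charts
#'
#' Reads the medial-lateral (ML) and anterior-posterior (AP) size charts of
#' the five supported manufacturer models (femur components and tibia
#' plates), transcribed from the manufacturers' surgical technique manuals.
#' One chart is the ordered list of sizes of one (manufacturer, component)
#' pair; chart order follows the printed size progression and defines the
#' size ordinal used for tie-breaks and the +/-1 accuracy band.
#'
#' @param path CSV path with columns `manufacturer, model, component,
#'   size_id, ML, AP`; `NULL` loads the packaged charts.
#' @return A list of `size_chart` objects (one per manufacturer and
#'   component), each a data frame with an added 0-based `ordinal` column.
#' @export
load_size_charts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "size_charts.csv", package = "tkrsize")
  }
  df <- utils::read.csv(path, check.names = TRUE, colClasses = "character")
  need <- c("manufacturer", "model", "component", "size_id", "ML", "AP")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("size chart is missing column(s): ", paste(missing_cols, collapse = ", "))
  df$ML <- as.numeric(df$ML)
  df$AP <- as.numeric(df$AP)
  if (any(!df$component %in% c("femur", "tibia")))
    stop("size chart row ", which(!df$component %in% c("femur", "tibia"))[1],
         ": component must be 'femur' or 'tibia'")
  bad <- which(!(df$ML > 0) | !(df$AP > 0))
  if (length(bad))
    stop("size chart row ", bad[1], ": non-positive dimension")
  key <- paste(df$manufacturer, df$component)
  charts <- lapply(split(df, factor(key, levels = unique(key))), function(ch) {
    ch$ordinal <- seq_len(nrow(ch)) - 1L
    if (anyDuplicated(ch$size_id)) {
      stop("size chart '", ch$manufacturer[1], " ", ch$component[1],
           "': duplicate size_id '", ch$size_id[anyDuplicated(ch$size_id)], "'")
    }
    if (nrow(ch) < 5L)
      stop("size chart '", ch$manufacturer[1], " ", ch$component[1],
           "' has fewer than 5 sizes")
    if (is.unsorted(ch$ML) || is.unsorted(ch$AP))
      stop("size chart '", ch$manufacturer[1], " ", ch$component[1],
           "': ML/AP must be non-decreasing in chart order")
    rownames(ch) <- NULL
    class(ch) <- c("size_chart", "data.frame")
    ch
  })
  names(charts) <- unique(key)
  charts
}

#' @export
print.size_chart <- function(x, ...) {
  cat(sprintf("size_chart: %s %s (%s), %d sizes\n", x$manufacturer[1],
              x$model[1], x$component[1], nrow(x)))
  print.data.frame(x[, c("size_id", "ML", "AP", "ordinal")], row.names = FALSE)
  invisible(x)
}

chart_entry <- function(chart, size_id) {
  i <- match(as.character(size_id), chart$size_id)
  if (is.na(i)) stop("unknown size_id '", size_id, "'")
  chart[i, , drop = FALSE]
}
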