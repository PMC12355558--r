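# Delimited-text readers/writers for count tables and results. The category
# columns are required by exact name and order (fail fast): a silently
# permuted column would corrupt the color-frequency estimates irrecoverably.

META_COLUMNS <- c("dataset_id", "induction_min", "stage", "image_class")

io_delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a category-count table
#'
#' Expects a UTF-8 delimited file (comma, or tab for `.tsv`/`.txt`) with a
#' header of the four metadata columns (`dataset_id`, `induction_min`,
#' `stage`, `image_class`) followed by the 15 category columns in canonical
#' order (G, R, Y, B, GR, ..., GRYB). Column order is validated, never
#' inferred; any missing, extra or misordered column is a hard error naming
#' the offender, as is any negative or non-integer count cell.
#'
#' @param path file path.
#' @return List of [category_counts()], one per row.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  space <- category_space()
  expected <- c(META_COLUMNS, as.character(space))
  df <- utils::read.table(path, header = TRUE, sep = io_delim(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  got <- names(df)
  if (!identical(got, expected)) {
    bad <- which(got[seq_along(expected)] != expected[seq_len(length(got))])
    detail <- if (length(got) != length(expected)) {
      sprintf("expected %d columns, found %d", length(expected), length(got))
    } else {
      sprintf("column %d is '%s', expected '%s'", bad[1], got[bad[1]],
              expected[bad[1]])
    }
    stop("count table header does not match the canonical layout (",
         detail, ")", call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("count table has a header but no data rows", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    cells <- df[i, as.character(space)]
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad)) {
      stop(sprintf("row %d: column '%s' has invalid count '%s' (need a non-negative integer)",
                   i, as.character(space)[bad[1]], cells[[bad[1]]]),
           call. = FALSE)
    }
    category_counts(vals,
                    dataset_id = df$dataset_id[i],
                    induction_min = suppressWarnings(as.numeric(df$induction_min[i])),
                    stage = df$stage[i],
                    image_class = df$image_class[i],
                    space = space)
  })
}

#' Write a category-count table
#'
#' Emits the canonical dialect read by [read_counts()];
#' `read_counts(write_counts(x, path))` round-trips exactly.
#'
#' @param datasets list of [category_counts()].
#' @param path output path (`.tsv`/`.txt` for tab-delimited, else comma).
#' @return `path`, invisibly.
#' @export
write_counts <- function(datasets, path) {
  if (!is.list(datasets) || length(datasets) == 0L ||
      !all(vapply(datasets, inherits, TRUE, "category_counts"))) {
    stop("`datasets` must be a non-empty list of category_counts", call. = FALSE)
  }
  space <- category_space()
  rows <- lapply(datasets, function(d) {
    data.frame(dataset_id = d$meta$dataset_id,
               induction_min = d$meta$induction_min,
               stage = d$meta$stage,
               image_class = d$meta$image_class,
               as.list(d$counts), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = io_delim(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

#' Write a results table with a structured sidecar
#'
#' The [fit_all()] table is serialized twice: a human-readable delimited table
#' at `path` (estimates at 6 significant digits, fixed column order, so the
#' bytes are a deterministic function of the table) and a JSON sidecar at
#' `<path>.json` holding the same rows at full precision plus the software
#' version, the fitting seed and confidence level — enough to re-run the fit
#' identically.
#'
#' @param table a `condition_table` from [fit_all()].
#' @param path output path for the delimited table.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(inherits(table, "condition_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE) & !names(df) %in% c("n_images", "induction_min")
  out <- df
  out[num] <- lapply(df[num], fmt6)
  utils::write.table(out, path, sep = io_delim(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  sidecar <- list(
    software = "clonecount",
    version = as.character(utils::packageVersion("clonecount")),
    seed = attr(table, "seed"),
    level = attr(table, "level"),
    rows = df
  )
  # 17 significant digits: lossless round-trip for IEEE doubles
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read back a results sidecar
#'
#' @param path the delimited-table path passed to [write_results()] (the
#'   `.json` sidecar next to it is read for full precision).
#' @return A `condition_table` equal to the one written.
#' @export
read_results <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("results sidecar not found: ", sidecar, call. = FALSE)
  obj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- as.data.frame(obj$rows, stringsAsFactors = FALSE)
  attr(tab, "seed") <- as.integer(obj$seed)
  attr(tab, "level") <- obj$level
  class(tab) <- c("condition_table", "data.frame")
  tab
}

#' Plot estimates across the experiment grid
#'
#' Point estimates of the mean founder-clone number with their profile
#' intervals, one panel position per induction time, colored by image class.
#'
#' @param table a `condition_table`.
#' @param ... passed to [graphics::plot()].
#' @return The table, invisibly.
#' @export
plot_condition_table <- function(table, ...) {
  stopifnot(inherits(table, "condition_table"))
  df <- as.data.frame(table)
  df <- df[!is.na(df$mu_hat), ]
  x <- seq_len(nrow(df))
  graphics::plot(x, df$mu_hat, ylim = range(0, df$mu_hi, na.rm = TRUE),
                 pch = ifelse(df$image_class == "tumor", 19, 1),
                 col = ifelse(df$stage == "late", "firebrick", "steelblue"),
                 xaxt = "n", xlab = "", ylab = "mean founder clones per image",
                 ...)
  graphics::segments(x, df$mu_lo, x, df$mu_hi,
                     col = ifelse(df$stage == "late", "firebrick", "steelblue"))
  graphics::axis(1, at = x, las = 2, cex.axis = 0.7,
                 labels = sprintf("%gm %s %s", df$induction_min, df$stage,
                                  df$image_class))
  graphics::legend("topleft", bty = "n", pch = c(19, 1, 19, 19),
                   col = c("black", "black", "firebrick", "steelblue"),
                   legend = c("tumor", "clone", "late", "early"))
  invisible(table)
}
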