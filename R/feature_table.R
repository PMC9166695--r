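#' Subject-by-feature table with modality/region/side annotations
#'
#' A `feature_table` holds one row per subject and one column per regional
#' imaging feature. Every column carries a modality label (e.g. `fALFF`,
#' `ReHo`, `GM_atrophy`, `GM_density`), a region name, a hemisphere side and
#' an anatomical class. Side labels are `L`/`R`/`mid` before treated-side
#' flipping and `TS`/`US`/`mid` after (treated / untreated side).
#'
#' @param values numeric matrix, subjects in rows (rownames = subject ids),
#'   features in columns.
#' @param annotations data frame with one row per column of `values` and
#'   columns `modality`, `region`, `side` and optionally `class`
#'   (`cortical`, `subcortical` or `cerebellar`).
#' @return An object of class `feature_table`: the value matrix with the
#'   annotation data frame attached.
#' @examples
#' ft <- feature_table(
#'   matrix(rnorm(4), 2, 2, dimnames = list(c("s1", "s2"), NULL)),
#'   data.frame(modality = "fALFF", region = c("ctx_01", "ctx_01"),
#'              side = c("L", "R")))
#' ft
#' @export
feature_table <- function(values, annotations) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  need <- c("modality", "region", "side")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotations lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(annotations) != ncol(values))
    stop("annotations (", nrow(annotations), " rows) do not match ",
         ncol(values), " feature columns")
  if (is.null(annotations$class)) annotations$class <- NA_character_
  key <- feature_key(annotations)
  if (anyDuplicated(key))
    stop("duplicated feature annotations: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sub", seq_len(nrow(values)))
  colnames(values) <- key
  structure(values, annotations = annotations, class = "feature_table")
}

feature_key <- function(ann) {
  paste(ann$modality, ann$region, ann$side, sep = "|")
}

#' @export
print.feature_table <- function(x, ...) {
  ann <- attr(x, "annotations")
  cat("feature_table: ", nrow(x), " subjects x ", ncol(x), " features\n",
      sep = "")
  tab <- table(ann$modality)
  cat("  modalities: ",
      paste(names(tab), " (", as.integer(tab), ")", sep = "", collapse = ", "),
      "\n  sides: ", paste(sort(unique(ann$side)), collapse = "/"), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.matrix.feature_table <- function(x, ...) {
  structure(unclass(x), annotations = NULL)
}

#' Annotations of a feature table
#' @param x a [feature_table].
#' @return The per-column annotation data frame.
#' @export
annotations <- function(x) attr(x, "annotations")

#' Mirror features of right-treated subjects onto a common orientation
#'
#' Subjects treated on the right side have the values of every homologous
#' left/right column pair swapped so that, for all subjects, the left
#' hemisphere holds the treated side. Columns are relabeled `TS` (treated
#' side) / `US` (untreated side); midline regions (side `mid`) pass through
#' unchanged.
#'
#' @param table a [feature_table] with sides in `L`/`R`/`mid`.
#' @param treated_side character vector (one of `"left"`/`"right"` per
#'   subject), recycled names must match the subject order of `table`.
#' @return A [feature_table] with sides `TS`/`US`/`mid`.
#' @export
flip_sides <- function(table, treated_side) {
  stopifnot(inherits(table, "feature_table"))
  ann <- annotations(table)
  if (!all(ann$side %in% c("L", "R", "mid")))
    stop("flip_sides expects sides labeled L/R/mid (already flipped?)")
  treated_side <- as.character(treated_side)
  if (length(treated_side) != nrow(table))
    stop("treated_side must give one of left/right per subject")
  if (!all(treated_side %in% c("left", "right")))
    stop("treated_side values must be 'left' or 'right'")

  lat <- ann$side %in% c("L", "R")
  pair_id <- paste(ann$modality, ann$region, sep = "|")
  # homologue lookup: for each lateralized column, the column with the
  # opposite side and same (modality, region)
  opp_side <- ifelse(ann$side == "L", "R", "L")
  opp_key <- paste(ann$modality, ann$region, opp_side, sep = "|")
  partner <- match(opp_key, feature_key(ann))
  bad <- lat & is.na(partner)
  if (any(bad))
    stop("lateralized region(s) without homologue: ",
         paste(unique(pair_id[bad]), collapse = ", "))

  vals <- as.matrix(table)
  right <- treated_side == "right"
  if (any(right) && any(lat)) {
    swapped <- vals[, partner[lat], drop = FALSE]
    vals[right, which(lat)] <- swapped[right, , drop = FALSE]
  }
  ann$side <- c(L = "TS", R = "US", mid = "mid")[ann$side]
  feature_table(vals, ann)
}

#' Longitudinal feature changes (month-4 minus baseline)
#'
#' @param baseline,month4 [feature_table]s with identical subject index and
#'   column annotations.
#' @return A [feature_table] of element-wise differences `month4 - baseline`.
#' @export
compute_changes <- function(baseline, month4) {
  stopifnot(inherits(baseline, "feature_table"), inherits(month4, "feature_table"))
  kb <- feature_key(annotations(baseline))
  km <- feature_key(annotations(month4))
  if (!identical(kb, km)) {
    d <- union(setdiff(kb, km), setdiff(km, kb))
    stop("column annotations differ between visits: ",
         paste(utils::head(d, 10), collapse = ", "),
         if (length(d) > 10) " ..." else "")
  }
  if (!identical(rownames(baseline), rownames(month4)))
    stop("subject index differs between visits: ",
         paste(union(setdiff(rownames(baseline), rownames(month4)),
                     setdiff(rownames(month4), rownames(baseline))),
               collapse = ", "))
  feature_table(as.matrix(month4) - as.matrix(baseline), annotations(baseline))
}

#' Write / read a feature table as annotated CSV
#'
#' The on-disk format has four annotation header rows (modality, region,
#' side, class) above the subject rows, first column = subject id; it
#' round-trips through [read_feature_table()].
#'
#' @param table a [feature_table].
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  ann <- annotations(table)
  hdr <- rbind(c("modality", ann$modality),
               c("region", ann$region),
               c("side", ann$side),
               c("class", as.character(ann$class)))
  body <- cbind(rownames(table), format(as.matrix(table), digits = 15, trim = TRUE))
  utils::write.table(rbind(hdr, body), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 5 || raw[1, 1] != "modality")
    stop("not a feature_table CSV: ", path)
  ann <- data.frame(modality = as.character(raw[1, -1]),
                    region = as.character(raw[2, -1]),
                    side = as.character(raw[3, -1]),
                    class = as.character(raw[4, -1]),
                    stringsAsFactors = FALSE)
  body <- raw[-(1:4), , drop = FALSE]
  vals <- apply(body[, -1, drop = FALSE], 2, as.numeric)
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(body[, 1], NULL))
  feature_table(vals, ann)
}
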