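#' Construct a peak table for one batch at one detection wavelength
#'
#' A peak table is the integrated result of one HPLC run: one row per detected
#' peak, with retention time (minutes) and integrated area. Rows are stored in
#' strictly increasing retention-time order.
#'
#' @param batch_id Character scalar identifying the batch.
#' @param wavelength Detection wavelength in nanometres (positive integer).
#' @param retention_time Numeric vector of retention times in minutes.
#' @param area Numeric vector of non-negative integrated peak areas.
#' @param peak_id Optional character vector of peak identifiers.
#' @return An object of class `peak_table`.
#' @examples
#' pt <- peak_table("S1", 260, c(5.2, 9.1, 14.3), c(120, 300, 80))
#' @export
peak_table <- function(batch_id, wavelength, retention_time, area,
                       peak_id = NULL) {
  if (!is.character(batch_id) || length(batch_id) != 1L) {
    fq_stop("'batch_id' must be a single character string")
  }
  if (!is_scalar_number(wavelength) || wavelength <= 0) {
    fq_stop("'wavelength' must be a single positive number (nm)")
  }
  if (!is.numeric(retention_time) || anyNA(rt <- as.numeric(retention_time))) {
    fq_stop("'retention_time' must be numeric without missing values")
  }
  if (length(area) != length(rt)) {
    fq_stop("'retention_time' and 'area' must have equal length")
  }
  bad <- which(!is.finite(area) | area < 0)
  if (length(bad)) {
    fq_stop(sprintf("negative or non-finite area at row %s",
                    paste(bad, collapse = ", ")))
  }
  if (is.null(peak_id)) peak_id <- rep(NA_character_, length(rt))
  ord <- order(rt)
  rt <- rt[ord]
  if (any(diff(rt) <= 0)) {
    fq_stop(sprintf("retention times must be strictly increasing in batch %s",
                    batch_id))
  }
  structure(
    list(batch_id = batch_id, wavelength = as.integer(wavelength),
         peaks = data.frame(peak_id = as.character(peak_id)[ord],
                            retention_time = rt,
                            area = as.numeric(area)[ord],
                            stringsAsFactors = FALSE)),
    class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> batch %s, %d nm, %d peaks\n",
              x$batch_id, x$wavelength, nrow(x$peaks)))
  invisible(x)
}

#' Read per-batch peak tables from a long-format CSV
#'
#' Expects columns `batch_id`, `wavelength`, `retention_time`, `area` and
#' optionally `peak_id` (names remappable through `schema`). One
#' [peak_table()] is returned per (batch, wavelength) pair, rows sorted by
#' retention time.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping the canonical column names to
#'   the names used in the file, e.g. `c(area = "Area")`.
#' @return A list of `peak_table` objects.
#' @seealso [write_peak_tables()]
#' @export
read_peak_tables <- function(path, schema = NULL) {
  if (!file.exists(path)) fq_stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cols <- c(batch_id = "batch_id", wavelength = "wavelength",
            retention_time = "retention_time", area = "area",
            peak_id = "peak_id")
  if (!is.null(schema)) cols[names(schema)] <- schema
  required <- cols[c("batch_id", "wavelength", "retention_time", "area")]
  missing <- required[!required %in% names(raw)]
  if (length(missing)) {
    fq_stop(sprintf("schema error: missing column '%s'", missing[[1]]))
  }
  rt <- suppressWarnings(as.numeric(raw[[cols[["retention_time"]]]]))
  if (anyNA(rt)) {
    fq_stop(sprintf("parse error: non-numeric retention time at row %s",
                    paste(which(is.na(rt)), collapse = ", ")))
  }
  area <- suppressWarnings(as.numeric(raw[[cols[["area"]]]]))
  if (anyNA(area)) {
    fq_stop(sprintf("parse error: non-numeric area at row %s",
                    paste(which(is.na(area)), collapse = ", ")))
  }
  bad <- which(area < 0)
  if (length(bad)) {
    fq_stop(sprintf("validation error: negative area at row %s",
                    paste(bad, collapse = ", ")))
  }
  wl <- suppressWarnings(as.numeric(raw[[cols[["wavelength"]]]]))
  if (anyNA(wl)) fq_stop("parse error: non-numeric wavelength")
  pid <- if (cols[["peak_id"]] %in% names(raw)) {
    raw[[cols[["peak_id"]]]]
  } else {
    rep(NA_character_, nrow(raw))
  }
  key <- paste(raw[[cols[["batch_id"]]]], wl, sep = "\r")
  idx <- split(seq_len(nrow(raw)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    peak_table(batch_id = raw[[cols[["batch_id"]]]][i][1],
               wavelength = wl[i][1],
               retention_time = rt[i], area = area[i], peak_id = pid[i])
  })
}

#' Write peak tables to a long-format CSV
#'
#' @param tables A `peak_table` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_tables <- function(tables, path) {
  if (inherits(tables, "peak_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(pt) {
    data.frame(batch_id = pt$batch_id, wavelength = pt$wavelength,
               retention_time = pt$peaks$retention_time,
               area = pt$peaks$area, peak_id = pt$peaks$peak_id,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct an aligned fingerprint matrix
#'
#' Holds the common-peak area vectors of B batches at one wavelength: the
#' sample fingerprint vectors x = (x1, ..., xn) that the similarity
#' computations operate on. Usually produced by [match_common_peaks()].
#'
#' @param wavelength Wavelength in nm.
#' @param batch_ids Character vector (length B).
#' @param peak_ids Character vector (length n >= 2).
#' @param areas Numeric B x n matrix of non-negative areas.
#' @param retention_times Numeric vector of n reference retention times.
#' @return An object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(wavelength, batch_ids, peak_ids, areas,
                               retention_times) {
  areas <- as.matrix(areas)
  B <- length(batch_ids); n <- length(peak_ids)
  if (B < 1L) fq_stop("need at least one batch")
  if (n < 2L) fq_stop("need at least two common peaks")
  if (!all(dim(areas) == c(B, n))) {
    fq_stop("'areas' must be a B x n matrix matching batch_ids/peak_ids")
  }
  check_area_vector(as.numeric(areas), "areas")
  if (any(rowSums(areas) == 0)) {
    fq_stop("fingerprint matrix contains an all-zero batch row")
  }
  if (length(retention_times) != n) {
    fq_stop("'retention_times' must have one entry per peak")
  }
  dimnames(areas) <- list(batch_ids, peak_ids)
  structure(
    list(wavelength = as.integer(wavelength),
         batch_ids = as.character(batch_ids),
         peak_ids = as.character(peak_ids),
         areas = areas,
         retention_times = as.numeric(retention_times)),
    class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d nm: %d batches x %d common peaks\n",
              x$wavelength, length(x$batch_ids), length(x$peak_ids)))
  invisible(x)
}

#' Match peaks common to every batch at one wavelength
#'
#' Clusters peaks greedily in retention-time order: a peak joins the open
#' cluster while it lies within `rt_tolerance` of the cluster's running
#' median retention time. A cluster is a common peak only if every batch
#' contributes exactly one member; clusters missing any batch are dropped,
#' and a batch contributing two peaks to one cluster is an ambiguity error.
#'
#' @param tables List of [peak_table()] objects sharing one wavelength.
#' @param rt_tolerance Retention-time tolerance in minutes (default 0.2).
#' @return A [fingerprint_matrix()] with columns ordered by reference
#'   retention time (per-cluster median) and batches in input order.
#' @export
match_common_peaks <- function(tables, rt_tolerance = 0.2) {
  if (inherits(tables, "peak_table")) tables <- list(tables)
  if (!length(tables)) fq_stop("no peak tables supplied")
  if (!is_scalar_number(rt_tolerance) || rt_tolerance <= 0) {
    fq_stop("'rt_tolerance' must be a positive number of minutes")
  }
  wls <- vapply(tables, function(t) t$wavelength, integer(1))
  if (length(unique(wls)) != 1L) {
    fq_stop("all peak tables must share one wavelength")
  }
  batch_ids <- vapply(tables, function(t) t$batch_id, character(1))
  if (anyDuplicated(batch_ids)) fq_stop("duplicated batch ids")

  pool <- do.call(rbind, lapply(seq_along(tables), function(i) {
    p <- tables[[i]]$peaks
    data.frame(batch = i, rt = p$retention_time, area = p$area,
               peak_id = p$peak_id, stringsAsFactors = FALSE)
  }))
  pool <- pool[order(pool$rt), ]

  clusters <- list()
  current <- integer(0)
  for (i in seq_len(nrow(pool))) {
    if (!length(current)) {
      current <- i
    } else if (abs(pool$rt[i] - stats::median(pool$rt[current])) <=
               rt_tolerance) {
      current <- c(current, i)
    } else {
      clusters[[length(clusters) + 1L]] <- current
      current <- i
    }
  }
  if (length(current)) clusters[[length(clusters) + 1L]] <- current

  keep <- list()
  for (cl in clusters) {
    counts <- tabulate(pool$batch[cl], nbins = length(tables))
    if (any(counts > 1L)) {
      b <- which(counts > 1L)[1]
      rts <- pool$rt[cl][pool$batch[cl] == b]
      fq_stop(sprintf(
        "ambiguous match: batch %s has %d peaks (RT %s min) in one cluster",
        batch_ids[b], length(rts),
        paste(format(rts, digits = 4), collapse = ", ")))
    }
    if (all(counts == 1L)) keep[[length(keep) + 1L]] <- cl
  }
  if (!length(keep)) {
    fq_stop("no peaks common to all batches within the given tolerance")
  }

  ref_rt <- vapply(keep, function(cl) stats::median(pool$rt[cl]), numeric(1))
  ord <- order(ref_rt)
  keep <- keep[ord]; ref_rt <- ref_rt[ord]

  peak_ids <- vapply(seq_along(keep), function(j) {
    ids <- pool$peak_id[keep[[j]]]
    ids <- ids[!is.na(ids) & nzchar(ids)]
    if (length(ids)) names(sort(table(ids), decreasing = TRUE))[1]
    else sprintf("P%02d", j)
  }, character(1))

  areas <- matrix(0, nrow = length(tables), ncol = length(keep))
  for (j in seq_along(keep)) {
    cl <- keep[[j]]
    areas[pool$batch[cl], j] <- pool$area[cl]
  }
  fingerprint_matrix(wavelength = wls[1], batch_ids = batch_ids,
                     peak_ids = peak_ids, areas = areas,
                     retention_times = ref_rt)
}

#' Average all batches into a reference fingerprint
#'
#' The reference fingerprint y = (y1, ..., yn) is the peak-wise arithmetic
#' mean over all batches of the matrix, every batch included (so evaluating
#' the reference against itself gives Sm = 1, Pm = 100 and alpha = 0).
#'
#' @param matrix A [fingerprint_matrix()].
#' @return An object of class `reference_fingerprint` with fields
#'   `wavelength`, `peak_ids`, `areas`.
#' @export
build_reference_fingerprint <- function(matrix) {
  if (!inherits(matrix, "fingerprint_matrix")) {
    fq_stop("'matrix' must be a fingerprint_matrix")
  }
  areas <- colMeans(matrix$areas)
  if (all(areas <= 0)) fq_stop("reference fingerprint has no positive entry")
  structure(list(wavelength = matrix$wavelength,
                 peak_ids = matrix$peak_ids,
                 areas = as.numeric(areas)),
            class = "reference_fingerprint")
}

#' Write / read a fingerprint matrix as wide CSV plus JSON sidecar
#'
#' The CSV holds one row per batch and one column per common peak; the
#' sidecar (`<path>.json`) records the wavelength, reference retention times
#' and any matching parameters.
#'
#' @param matrix A [fingerprint_matrix()].
#' @param path CSV output path.
#' @param params Optional list of matching parameters to record.
#' @return `path`, invisibly.
#' @export
write_fingerprint_matrix <- function(matrix, path, params = list()) {
  df <- data.frame(batch_id = matrix$batch_ids, matrix$areas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(wavelength = matrix$wavelength,
                  peak_ids = matrix$peak_ids,
                  retention_times = matrix$retention_times,
                  params = params)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fingerprint_matrix
#' @export
read_fingerprint_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fingerprint_matrix(wavelength = side$wavelength,
                     batch_ids = df$batch_id,
                     peak_ids = side$peak_ids,
                     areas = as.matrix(df[, -1, drop = FALSE]),
                     retention_times = side$retention_times)
}
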