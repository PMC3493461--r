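#' Load-set databases
#'
#' One load set is a single experiment record: three commanded input
#' tensions (with their fixed angles), the two measured grounded reaction
#' magnitudes, and the six input-to-output inter-nodal distances at
#' equilibrium.  A database is an ordered collection of such records
#' tagged `"training"` or `"cross_validation"`, plus the bookkeeping of
#' which training records have been exposed (served) to the inference loop
#' so far.
#'
#' @param records data.frame with columns `set_id`, `tag`, `F1`..`F3` (N),
#'   `ang1`..`ang3` (degrees), `R1`, `R2` (N), `d11`, `d12`, `d21`, `d22`,
#'   `d31`, `d32` (mm).
#' @param exposed integer vector of row indices of training records already
#'   served, in serving order.
#' @return object of class `sn_loadset_db`.
#' @export
new_loadset_db <- function(records, exposed = integer(0)) {
  db <- structure(list(records = as.data.frame(records),
                       exposed = as.integer(exposed)),
                  class = "sn_loadset_db")
  validate_loadset_db(db)
}

loadset_cols <- c("set_id", "tag", "F1", "F2", "F3", "ang1", "ang2", "ang3",
                  "R1", "R2", "d11", "d12", "d21", "d22", "d31", "d32")

#' @rdname new_loadset_db
#' @param db an `sn_loadset_db`.
#' @export
validate_loadset_db <- function(db) {
  rec <- db$records
  miss <- setdiff(loadset_cols, names(rec))
  if (length(miss))
    stop("load-set validation: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(rec)) {
    F <- as.matrix(rec[, c("F1", "F2", "F3")])
    bad <- which(apply(F, 1, function(f) any(f < 0 | f > 5)))
    if (length(bad))
      stop("load-set validation: input magnitude outside [0, 5] N at row ",
           bad[1], call. = FALSE)
    bad <- which(rec$R1 < 0 | rec$R2 < 0)
    if (length(bad))
      stop("load-set validation: negative reaction at row ", bad[1],
           call. = FALSE)
    D <- as.matrix(rec[, c("d11", "d12", "d21", "d22", "d31", "d32")])
    bad <- which(apply(D, 1, function(d) any(d <= 0)))
    if (length(bad))
      stop("load-set validation: non-positive distance at row ", bad[1],
           call. = FALSE)
    if (!all(rec$tag %in% c("training", "cross_validation")))
      stop("load-set validation: tag must be training/cross_validation",
           call. = FALSE)
  }
  if (length(db$exposed)) {
    if (any(db$exposed < 1 | db$exposed > nrow(rec)))
      stop("load-set validation: exposed index out of range", call. = FALSE)
    if (any(rec$tag[db$exposed] != "training"))
      stop("load-set validation: cross-validation record marked exposed",
           call. = FALSE)
  }
  db
}

#' @export
print.sn_loadset_db <- function(x, ...) {
  cat(sprintf("<sn_loadset_db> %d records (%d training, %d cross-validation), %d exposed\n",
              nrow(x$records), sum(x$records$tag == "training"),
              sum(x$records$tag == "cross_validation"), length(x$exposed)))
  invisible(x)
}

#' Subsets of a database
#'
#' `training_records` / `cv_records` return the training and
#' cross-validation rows; `exposed_records` the served training rows in
#' serving order (all training rows if none have been marked exposed,
#' which is the off-line whole-grid use).
#'
#' @param db an `sn_loadset_db`.
#' @return a data.frame of records.
#' @export
training_records <- function(db) db$records[db$records$tag == "training", ]

#' @rdname training_records
#' @export
cv_records <- function(db) db$records[db$records$tag == "cross_validation", ]

#' @rdname training_records
#' @export
exposed_records <- function(db) {
  if (length(db$exposed)) db$records[db$exposed, ] else training_records(db)
}

#' Save / load a load-set database
#'
#' JSON round trip is lossless, including tags, record order and the
#' exposed bookkeeping.  `save_loadsets_csv` writes the flat CSV export
#' (columns `set_id, tag, F1_N..F3_N, ang1_deg..ang3_deg, R1_N, R2_N,
#' d11_mm..d32_mm`).
#'
#' @param db an `sn_loadset_db`.
#' @param path file path.
#' @export
save_loadsets <- function(db, path) {
  validate_loadset_db(db)
  jsonlite::write_json(list(records = db$records, exposed = db$exposed),
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_loadsets
#' @export
load_loadsets <- function(path) {
  if (!file.exists(path)) stop("load-set file not found: ", path,
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  rec <- obj$records
  if (is.null(rec) || (!is.data.frame(rec) && length(rec) == 0))
    rec <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(loadset_cols))), loadset_cols)
  new_loadset_db(rec, exposed = as.integer(obj$exposed))
}

#' @rdname save_loadsets
#' @export
save_loadsets_csv <- function(db, path) {
  rec <- db$records
  out <- data.frame(set_id = rec$set_id, tag = rec$tag,
                    F1_N = rec$F1, F2_N = rec$F2, F3_N = rec$F3,
                    ang1_deg = rec$ang1, ang2_deg = rec$ang2,
                    ang3_deg = rec$ang3, R1_N = rec$R1, R2_N = rec$R2,
                    d11_mm = rec$d11, d12_mm = rec$d12, d21_mm = rec$d21,
                    d22_mm = rec$d22, d31_mm = rec$d31, d32_mm = rec$d32)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
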