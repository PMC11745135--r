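#' The closed trait vocabulary
#'
#' Eight linear measurements (mm) used throughout: total length (`toL`),
#' carapace length (`carL`), chela length/width (`cheL`, `cheW`), metasomal
#' segment V length/width (`met5L`, `met5W`), telson length/width
#' (`teL`, `teW`).
#'
#' @return Character vector of the eight trait names.
#' @export
trait_names <- function() {
  c("toL", "carL", "cheL", "cheW", "met5L", "met5W", "teL", "teW")
}

.SEXES <- c("female", "male")

#' Construct a species-by-trait matrix
#'
#' One row per species-sex combination, one column per trait. Missing cells
#' are `NA`. Values are strictly positive millimetres, or log-millimetres
#' when `scale = "log"`.
#'
#' @param data Data frame with columns `species`, `sex` and any subset of
#'   [trait_names()]. Unknown trait columns are rejected.
#' @param scale `"mm"` or `"log"`.
#' @return Object of class `"trait_matrix"`: the validated data frame with a
#'   `scale` attribute.
#' @export
trait_matrix <- function(data, scale = c("mm", "log")) {
  scale <- match.arg(scale)
  data <- as.data.frame(data)
  if (!all(c("species", "sex") %in% names(data))) {
    stop("data needs 'species' and 'sex' columns")
  }
  extra <- setdiff(names(data), c("species", "sex", trait_names()))
  if (length(extra) > 0L) {
    stop("unknown trait columns: ", paste(extra, collapse = ", "),
         " (allowed: ", paste(trait_names(), collapse = ", "), ")")
  }
  bad_sex <- setdiff(unique(data$sex), .SEXES)
  if (length(bad_sex) > 0L) {
    stop("sex must be one of: ", paste(.SEXES, collapse = ", "))
  }
  if (anyDuplicated(data[c("species", "sex")])) {
    stop("duplicated species-sex rows")
  }
  tcols <- intersect(trait_names(), names(data))
  if (scale == "mm") {
    vals <- as.matrix(data[tcols])
    if (any(vals <= 0, na.rm = TRUE)) {
      stop("mm trait values must be positive")
    }
  }
  data <- data[c("species", "sex", tcols)]
  rownames(data) <- NULL
  structure(data, class = c("trait_matrix", "data.frame"), scale = scale)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Trait matrix (", attr(x, "scale"), " scale): ",
      length(unique(x$species)), " species, ", nrow(x), " species-sex rows\n",
      sep = "")
  NextMethod()
}

#' Scale of a trait matrix
#' @param x A `"trait_matrix"`.
#' @return `"mm"` or `"log"`.
#' @export
trait_scale <- function(x) attr(x, "scale")

#' Trait columns of a trait matrix as a numeric matrix
#' @param x A `"trait_matrix"`.
#' @return Numeric matrix, rows named `species|sex`.
#' @export
trait_values <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  m <- as.matrix(as.data.frame(x)[intersect(trait_names(), names(x))])
  rownames(m) <- paste(x$species, x$sex, sep = "|")
  m
}

#' Species means from individual measurement records
#'
#' Aggregates raw individual measurements (long format: one row per measured
#' individual and trait) into per-species, per-sex arithmetic means on the
#' raw millimetre scale. Cells with no records are missing.
#'
#' @param records Data frame with columns `species`, `sex`, `trait`,
#'   `value_mm`.
#' @return A `"trait_matrix"` on the mm scale.
#' @export
species_means <- function(records) {
  need <- c("species", "sex", "trait", "value_mm")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.na(records$value_mm) & records$value_mm <= 0)
  if (length(bad) > 0L) {
    stop("nonpositive value_mm at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  unknown <- setdiff(unique(records$trait), trait_names())
  if (length(unknown) > 0L) {
    stop("unknown trait(s): ", paste(unknown, collapse = ", "))
  }
  records <- records[!is.na(records$value_mm), , drop = FALSE]
  agg <- stats::aggregate(value_mm ~ species + sex + trait, data = records,
                          FUN = mean)
  wide <- stats::reshape(agg, direction = "wide",
                         idvar = c("species", "sex"), timevar = "trait")
  names(wide) <- sub("^value_mm\\.", "", names(wide))
  present <- intersect(trait_names(), names(wide))
  wide <- wide[order(wide$species, wide$sex), c("species", "sex", present)]
  trait_matrix(wide, scale = "mm")
}

#' Natural-log transform of a trait matrix
#'
#' @param x A `"trait_matrix"` on the mm scale.
#' @return The matrix with every present cell replaced by its natural log,
#'   flagged as log scale. Missingness is unchanged.
#' @export
to_log <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  if (trait_scale(x) != "mm") stop("matrix is already on the log scale")
  tcols <- intersect(trait_names(), names(x))
  out <- as.data.frame(x)
  out[tcols] <- lapply(out[tcols], log)
  trait_matrix(out, scale = "log")
}

#' Inverse of [to_log()]
#'
#' @param x A `"trait_matrix"` on the log scale.
#' @return The matrix back on the mm scale (`exp` of every present cell).
#' @export
to_mm <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  if (trait_scale(x) != "log") stop("matrix is not on the log scale")
  tcols <- intersect(trait_names(), names(x))
  out <- as.data.frame(x)
  out[tcols] <- lapply(out[tcols], exp)
  trait_matrix(out, scale = "mm")
}

#' Per-trait missingness report
#'
#' Fraction of missing cells per trait and sex, relative to the number of
#' species rows of that sex.
#'
#' @param x A `"trait_matrix"`.
#' @return Data frame with columns `sex`, `trait`, `n_missing`, `n_species`,
#'   `fraction`.
#' @export
missingness_report <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  tcols <- intersect(trait_names(), names(x))
  out <- list()
  for (s in intersect(.SEXES, unique(x$sex))) {
    sub <- as.data.frame(x)[x$sex == s, tcols, drop = FALSE]
    n <- nrow(sub)
    miss <- vapply(sub, function(v) sum(is.na(v)), integer(1))
    out[[s]] <- data.frame(sex = s, trait = tcols,
                           n_missing = unname(miss), n_species = n,
                           fraction = unname(miss) / n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write trait tables
#'
#' Two CSV schemas are supported: long individual records
#' (`species,sex,trait,value_mm`) and wide species-mean matrices (one row
#' per species-sex, one column per trait; empty cell = missing).
#'
#' @param path CSV path.
#' @param scale Scale flag for the wide schema.
#' @return `read_records`: a data frame of individual records;
#'   `read_trait_matrix`: a `"trait_matrix"`.
#' @name trait_io
NULL

#' @rdname trait_io
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "sex", "trait", "value_mm")
  if (!all(need %in% names(rec))) {
    stop("records CSV needs columns: ", paste(need, collapse = ", "))
  }
  rec
}

#' @rdname trait_io
#' @export
read_trait_matrix <- function(path, scale = c("mm", "log")) {
  trait_matrix(utils::read.csv(path, stringsAsFactors = FALSE),
               scale = match.arg(scale))
}

#' @rdname trait_io
#' @param x A `"trait_matrix"` or record data frame to write.
#' @export
write_trait_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
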