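#' Per-patient trial tables
#'
#' A `trial_table` is the single input currency of the package: one row per
#' patient, with a binary outcome `Y` (1 = success, e.g. sinus rhythm at one
#' year), a binary mediator `M` (1 = co-intervention received, e.g. LAA
#' removed), a binary treatment indicator `T` (1 = intervention arm), a
#' `cluster` label identifying the operating surgeon, and any number of
#' baseline covariate columns.  Covariates are continuous or 0/1; categorical
#' covariates declared in the schema are expanded to reference-level dummy
#' columns named `<covariate>_<level>` at construction, with the reference
#' being the first level in sorted order unless the schema says otherwise.
#'
#' The complete-case contract is enforced at construction: missing values in
#' `Y`, `M`, `T` or `cluster` are rejected, as are tables with an empty arm or
#' fewer than two clusters.  Cluster labels are opaque strings, never assumed
#' numeric or ordered.
#'
#' @param data a data.frame with columns `Y`, `M`, `T`, `cluster` and
#'   covariates.
#' @param schema optional named list describing covariates.  Each element is
#'   either a type string (`"continuous"` or `"binary"`) or, for categorical
#'   covariates, a list with elements `type = "categorical"`, optional
#'   `levels` and optional `ref` (reference level).  Covariates absent from
#'   the schema have their type inferred (0/1 numeric -> binary, other
#'   numeric -> continuous).
#' @return an object of class `trial_table`: the validated (and
#'   dummy-expanded) data.frame with attributes `schema` (covariate name ->
#'   type), `arm_sizes` (named numeric, `"0"` and `"1"`) and `cluster_index`
#'   (named list of row positions per cluster label).
#' @examples
#' tab <- trial_table(data.frame(
#'   Y = c(1, 0, 1, 0), M = c(1, 0, 0, 1), T = c(1, 1, 0, 0),
#'   cluster = c("a", "a", "b", "b"), age = c(70, 65, 72, 80)))
#' summarize_arms(tab)
#' @export
trial_table <- function(data, schema = NULL) {
  if (!is.data.frame(data)) stop_msg("`data` must be a data.frame")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("Y", "M", "T", "cluster")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_msg("schema error: missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(names(data))) {
    stop_msg("covariate names must be unique; duplicated: ",
             paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  }
  for (col in c("Y", "M", "T")) {
    v <- data[[col]]
    if (anyNA(v)) {
      stop_msg("missing values in '", col, "' (rows ",
               paste(which(is.na(v)), collapse = ", "),
               "); complete cases are required")
    }
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad)) {
      stop_msg("value error: column '", col, "' must be 0/1; offending row(s): ",
               paste(utils::head(bad, 5), collapse = ", "))
    }
    data[[col]] <- as.integer(v)
  }
  data$cluster <- as.character(data$cluster)
  if (anyNA(data$cluster) || any(!nzchar(data$cluster))) {
    stop_msg("cluster labels must be non-empty and non-missing")
  }

  cov_names <- setdiff(names(data), required)
  out <- data[required]
  schema_out <- list()
  for (nm in cov_names) {
    sch <- schema[[nm]]
    v <- data[[nm]]
    type <- if (is.null(sch)) {
      if (is.numeric(v) && all(v %in% c(0, 1))) "binary"
      else if (is.numeric(v)) "continuous"
      else "categorical"
    } else if (is.character(sch)) sch else sch$type
    if (type %in% c("continuous", "binary")) {
      if (!is.numeric(v)) stop_msg("covariate '", nm, "' declared ", type,
                                   " but is not numeric")
      if (anyNA(v)) stop_msg("missing values in covariate '", nm, "'")
      if (type == "binary" && !all(v %in% c(0, 1))) {
        stop_msg("value error: binary covariate '", nm, "' has non-0/1 values")
      }
      out[[nm]] <- as.numeric(v)
      schema_out[[nm]] <- type
    } else if (identical(type, "categorical")) {
      v <- as.character(v)
      if (anyNA(v)) stop_msg("missing values in covariate '", nm, "'")
      levs <- if (!is.null(sch) && is.list(sch) && !is.null(sch$levels)) {
        sch$levels
      } else sort(unique(v))
      if (!all(v %in% levs)) {
        stop_msg("covariate '", nm, "' has values outside declared levels: ",
                 paste(setdiff(unique(v), levs), collapse = ", "))
      }
      ref <- if (!is.null(sch) && is.list(sch) && !is.null(sch$ref)) {
        sch$ref
      } else levs[1L]
      for (lv in setdiff(levs, ref)) {
        dname <- paste0(nm, "_", lv)
        out[[dname]] <- as.numeric(v == lv)
        schema_out[[dname]] <- "binary"
      }
    } else {
      stop_msg("unknown covariate type '", type, "' for '", nm, "'")
    }
  }

  arm_sizes <- c(`0` = sum(out$T == 0L), `1` = sum(out$T == 1L))
  if (any(arm_sizes == 0)) stop_msg("validation error: both arms must be non-empty")
  cluster_index <- split(seq_len(nrow(out)), out$cluster)
  if (length(cluster_index) < 2L) {
    stop_msg("validation error: at least 2 clusters are required (found ",
             length(cluster_index), ")")
  }
  structure(out,
            schema = schema_out,
            arm_sizes = arm_sizes,
            cluster_index = cluster_index,
            class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d patients, %d clusters (arm sizes %d/%d)\n",
              nrow(x), length(attr(x, "cluster_index")),
              attr(x, "arm_sizes")[["0"]], attr(x, "arm_sizes")[["1"]]))
  covs <- covariate_names(x)
  cat("Covariates:",
      if (length(covs)) paste(covs, collapse = ", ") else "(none)", "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Covariate column names of a trial table
#' @param table a `trial_table`.
#' @return character vector (possibly empty) of covariate columns.
#' @export
covariate_names <- function(table) {
  setdiff(names(table), c("Y", "M", "T", "cluster"))
}

#' Read a per-patient trial table from CSV
#'
#' Expects a comma-delimited UTF-8 file with a header row naming `Y`, `M`,
#' `T`, `cluster` and covariate columns.  Validation and categorical dummy
#' expansion are as in [trial_table()]; row order is preserved.
#'
#' @param path path to the CSV file.
#' @param schema optional covariate schema, see [trial_table()].
#' @return a validated `trial_table`.
#' @export
read_trial_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_msg("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cluster = "character"),
                        check.names = FALSE, fileEncoding = "UTF-8")
  trial_table(df, schema = schema)
}

#' Write a trial table to CSV
#'
#' Writes the (dummy-expanded) table as comma-delimited UTF-8 text that
#' [read_trial_table()] reads back to an identical table.
#'
#' @param table a `trial_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  ok <- tryCatch({
    utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_msg("could not write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Arm-level and cluster-level summary of a trial table
#'
#' Reports, for each arm, the number of patients, the count and proportion of
#' successful outcomes (`Y = 1`) and of mediator uptake (`M = 1`), and for
#' each surgeon cluster its size and mediator uptake.  Proportions are exact
#' count ratios; rounding happens only when printing.
#'
#' @param table a `trial_table`.
#' @return an `arm_summary` object: a list with data.frames `arms` (columns
#'   `arm`, `n`, `y_count`, `y_prop`, `m_count`, `m_prop`) and `clusters`
#'   (columns `cluster`, `n`, `m_count`, `m_prop`).
#' @examples
#' # The motivating trial reported 84/137 (61.3%) successes under ablation:
#' tab <- trial_table(data.frame(
#'   Y = c(rep(1, 84), rep(0, 53), rep(1, 67), rep(0, 76)),
#'   M = 0, T = rep(c(1, 0), c(137, 143)),
#'   cluster = rep(c("s1", "s2"), length.out = 280)))
#' summarize_arms(tab)$arms$y_prop
#' @export
summarize_arms <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  arms <- do.call(rbind, lapply(c(0L, 1L), function(a) {
    idx <- table$T == a
    data.frame(arm = a, n = sum(idx),
               y_count = sum(table$Y[idx]),
               y_prop = sum(table$Y[idx]) / sum(idx),
               m_count = sum(table$M[idx]),
               m_prop = sum(table$M[idx]) / sum(idx))
  }))
  cl <- attr(table, "cluster_index")
  clusters <- do.call(rbind, lapply(names(cl), function(lab) {
    idx <- cl[[lab]]
    data.frame(cluster = lab, n = length(idx),
               m_count = sum(table$M[idx]),
               m_prop = sum(table$M[idx]) / length(idx))
  }))
  structure(list(arms = arms, clusters = clusters), class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, digits = 3, ...) {
  cat("Arm summary\n")
  a <- x$arms
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  arm %d: n=%d  Y=1: %d (%.1f%%)  M=1: %d (%.1f%%)\n",
                a$arm[i], a$n[i], a$y_count[i], 100 * a$y_prop[i],
                a$m_count[i], 100 * a$m_prop[i]))
  }
  cat(sprintf("Clusters: %d (size %d-%d), mediator uptake %.1f%%-%.1f%%\n",
              nrow(x$clusters), min(x$clusters$n), max(x$clusters$n),
              100 * min(x$clusters$m_prop), 100 * max(x$clusters$m_prop)))
  invisible(x)
}

#' @export
summary.trial_table <- function(object, ...) summarize_arms(object)
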