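#' Typed data set of individuals by variables
#'
#' A thin wrapper around a `data.frame` that records, per variable, its kind
#' (`"continuous"` or `"categorical"`) and its role in the causal design
#' (`"instrument"`, `"phenotype"`, `"outcome"`, `"confounder"` or `"score"`).
#' All downstream machinery (network scoring, MR engines, the evaluation
#' harness) reads kinds and roles from these attributes, so a data set built
#' here can be passed around without extra metadata arguments.
#'
#' Categorical variables are stored as integer codes; their declared level
#' sets live in the `"levels"` attribute (a named list). Genotype columns are
#' continuous-or-categorical depending on how the study treats them: the
#' quantitative-trait study scores every node as Gaussian, the binary study
#' as multinomial.
#'
#' @param values data.frame of numeric columns, one row per individual.
#' @param kind named character vector mapping each column to
#'   `"continuous"` or `"categorical"`. Unnamed scalar recycles to all.
#' @param role named character vector mapping columns to roles; defaults to
#'   `"phenotype"` for unspecified columns.
#' @param levels named list of level sets for categorical columns; defaults
#'   to the sorted unique values observed.
#' @return the data.frame with class `"anchor_dataset"` and metadata
#'   attributes attached.
#' @export
as_dataset <- function(values, kind = "continuous", role = NULL, levels = NULL) {
  stopifnot(is.data.frame(values), nrow(values) >= 1L)
  vn <- names(values)
  if (anyNA(values)) stop("data set must not contain missing values")
  kind <- expand_named(kind, vn, default = "continuous")
  bad <- setdiff(unique(kind), c("continuous", "categorical"))
  if (length(bad)) stop("unknown variable kind: ", paste(bad, collapse = ", "))
  role <- expand_named(role, vn, default = "phenotype")
  lev <- stats::setNames(vector("list", length(vn)), vn)
  for (v in vn[kind == "categorical"]) {
    lev[[v]] <- if (!is.null(levels[[v]])) sort(levels[[v]]) else sort(unique(values[[v]]))
    if (!all(values[[v]] %in% lev[[v]]))
      stop("values of categorical variable '", v, "' outside declared levels")
  }
  structure(values, kind = kind, role = role, levels = lev,
            class = c("anchor_dataset", "data.frame"))
}

expand_named <- function(x, vn, default) {
  out <- stats::setNames(rep(default, length(vn)), vn)
  if (is.null(x)) return(out)
  if (is.null(names(x))) {
    if (length(x) == 1L) out[] <- x else {
      stopifnot(length(x) == length(vn))
      out[] <- x
    }
  } else {
    stopifnot(all(names(x) %in% vn))
    out[names(x)] <- x
  }
  out
}

#' @export
#' @rdname as_dataset
#' @param data an `anchor_dataset` (or plain data.frame, for which defaults
#'   are returned).
dataset_kind <- function(data) {
  k <- attr(data, "kind")
  if (is.null(k)) k <- stats::setNames(rep("continuous", ncol(data)), names(data))
  k
}

#' @export
#' @rdname as_dataset
dataset_role <- function(data) {
  r <- attr(data, "role")
  if (is.null(r)) r <- stats::setNames(rep("phenotype", ncol(data)), names(data))
  r
}

#' @export
#' @rdname as_dataset
dataset_levels <- function(data) {
  lev <- attr(data, "levels")
  if (is.null(lev)) lev <- stats::setNames(vector("list", ncol(data)), names(data))
  k <- dataset_kind(data)
  for (v in names(data)[k == "categorical"]) {
    if (is.null(lev[[v]])) lev[[v]] <- sort(unique(data[[v]]))
  }
  lev
}

# keep attributes when subsetting columns
#' @export
`[.anchor_dataset` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    vn <- names(out)
    out <- structure(as.data.frame(out),
                     kind = dataset_kind(x)[vn],
                     role = dataset_role(x)[vn],
                     levels = dataset_levels(x)[vn],
                     class = c("anchor_dataset", "data.frame"))
  }
  out
}

#' Write / read a data set as CSV plus a JSON metadata side-car
#'
#' The CSV holds the values with a header row; `<path>.meta.json` records
#' each column's kind, role and (for categorical columns) level set, so a
#' round trip preserves the typed data set exactly.
#'
#' @param data an `anchor_dataset`.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   an `anchor_dataset`.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- list(kind = as.list(dataset_kind(data)),
               role = as.list(dataset_role(data)),
               levels = dataset_levels(data))
  writeLines(to_json(meta), paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  values <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path) && requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    as_dataset(values, kind = unlist(meta$kind), role = unlist(meta$role),
               levels = as.list(meta$levels))
  } else {
    as_dataset(values)
  }
}

# minimal JSON writer for the metadata side-car (kept dependency-free;
# jsonlite is only needed to read it back)
to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  f <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v)) {
      if (is.null(names(v)))
        return(paste0("[", paste(vapply(v, f, ""), collapse = ","), "]"))
      return(paste0("{", paste0('"', esc(names(v)), '":',
                                vapply(v, f, ""), collapse = ","), "}"))
    }
    if (is.character(v)) {
      s <- paste0('"', esc(v), '"')
    } else {
      s <- as.character(v)
    }
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ","), "]")
  }
  f(x)
}
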