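#' Columns of a leaf-sample trait table
#'
#' One row per leaf sample: taxonomy (`species`, `family`), plant
#' `group` (Eu/Se/Ps/Gl), `site` and `individual` identifiers, leaf
#' `status` (green/senesced), the six element concentrations in
#' mg g^-1, and morphology (`leaf_area` cm^2, `dry_mass` g,
#' `saturated_mass` g).
#'
#' @return Character vector of mandatory column names.
#' @export
trait_table_columns <- function() {
  c("species", "family", "group", "site", "individual", "status",
    resorb_elements(), "leaf_area", "dry_mass", "saturated_mass")
}

#' Read a leaf-trait table from CSV
#'
#' Reads a long-format leaf-sample table (comma-separated, UTF-8, "."
#' decimal, header mandatory) and validates each row against the
#' leaf-sample invariants: element concentrations >= 0,
#' 0 < dry_mass <= saturated_mass, leaf_area > 0, status in
#' {green, senesced}.  Rows violating an invariant are rejected with a
#' row-number diagnostic and returned in the `rejections` attribute;
#' a structural problem (missing mandatory column, unknown plant-group
#' label) is an error.
#'
#' @param path CSV file path.
#' @return A `data.frame` of accepted rows with attributes
#'   `n_accepted`, `n_rejected` and `rejections` (a data.frame with
#'   columns `row` and `reason`).
#' @export
read_trait_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(trait_table_columns(), names(raw))
  if (length(missing_cols)) {
    stop("trait table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  bad_group <- setdiff(unique(raw$group), resorb_groups())
  if (length(bad_group)) {
    stop("unknown plant group label(s): ",
         paste(bad_group, collapse = ", "))
  }
  validate_leaf_samples(raw[, trait_table_columns(), drop = FALSE])
}

# Row-level invariant check shared by the reader and the generator.
validate_leaf_samples <- function(df) {
  reasons <- character(nrow(df))
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  flag(!(df$status %in% c("green", "senesced")),
       "status must be 'green' or 'senesced'")
  conc <- as.matrix(df[, resorb_elements(), drop = FALSE])
  flag(apply(!is.finite(conc) | conc < 0, 1L, any),
       "element concentration missing or negative")
  flag(!is.finite(df$dry_mass) | df$dry_mass <= 0, "dry_mass must be > 0")
  flag(!is.finite(df$saturated_mass) | df$dry_mass > df$saturated_mass,
       "dry_mass exceeds saturated_mass")
  flag(!is.finite(df$leaf_area) | df$leaf_area <= 0, "leaf_area must be > 0")
  rejected <- nzchar(reasons)
  out <- df[!rejected, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_accepted") <- nrow(out)
  attr(out, "n_rejected") <- sum(rejected)
  attr(out, "rejections") <- data.frame(row = which(rejected),
                                        reason = reasons[rejected])
  if (any(rejected)) {
    warning(sum(rejected), " row(s) rejected: ",
            paste0("row ", which(rejected), ": ", reasons[rejected],
                   collapse = "; "), call. = FALSE)
  }
  out
}

# Format a data.frame for CSV so that doubles survive a write/read
# round trip bit-exactly (17 significant digits).
.format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a leaf-trait table to CSV
#'
#' Inverse of [read_trait_table()]; numeric columns are written with 17
#' significant digits so accepted rows round-trip bit-exactly.
#'
#' @param samples Leaf-sample data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(samples, path) {
  df <- as.data.frame(samples)[, trait_table_columns(), drop = FALSE]
  utils::write.csv(.format_full_precision(df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables and run metadata to a directory
#'
#' Writes one CSV per named table (full numeric precision, deterministic
#' formatting: identical inputs give byte-identical files) plus a
#' `run_metadata.json` recording the seed, package and R versions and
#' the configuration.  Empty tables produce a header-only CSV with a
#' warning.
#'
#' @param tables Named list of data.frames.
#' @param outdir Output directory, created if needed.
#' @param seed Integer seed used for the run (recorded in metadata).
#' @param config Configuration list echoed into the metadata.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, outdir, seed = NULL, config = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (nrow(tab) == 0L) {
      warning("result table '", nm, "' is empty; writing header only",
              call. = FALSE)
    }
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(.format_full_precision(tab), f,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  meta <- list(
    seed = seed,
    package = "resorb",
    package_version = as.character(utils::packageVersion("resorb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    tables = names(tables),
    config = config
  )
  mf <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(files, mf))
}
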