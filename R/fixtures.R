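#' Built-in example networks
#'
#' Named partitions covering the canonical textbook motifs, shipped as
#' canonical partition JSON under `inst/extdata/partitions/` and built
#' programmatically at package build time:
#'
#' * `fig1a` activation chain: product of reaction 1 is the enzyme of
#'   reaction 2 (N = 2)
#' * `fig1b` two-step reaction, `fig1c` branching, `fig1d` confluence (N = 2)
#' * `fig1e` autocatalysis, `fig1f` association-dissociation,
#'   `fig1g` dimer formation-separation (N = 1)
#' * `fig2a` two auto-activating, mutually inhibitory cyclic reaction
#'   systems — the classic resettable bistable motif (N = 4)
#' * `fig2b` the MAPK cascade as an N = 10 partition (14 blocks)
#' * `fig3A`, `fig3B`, `fig3C` the distance worked example (N = 2)
#' * `reference_config` the default [search_config()]
#'
#' Every partition fixture round-trips unchanged through the JSON
#' reader/writer. A fixture is flagged `searchable` when the default input
#' (`E1`) and output (`P2`) both exist in its universe and sit in distinct
#' blocks.
#'
#' @param name fixture name, e.g. `"fig2a"`.
#' @return A `ptm_partition` (with attributes `fixture` and `searchable`)
#'   or, for `"reference_config"`, a `ptm_search_config`.
#' @examples
#' load_fixture("fig2a")
#' @export
load_fixture <- function(name) {
  if (identical(name, "reference_config")) return(search_config())
  catalog <- fixture_catalog()
  if (!name %in% names(catalog)) {
    stop("unknown fixture \"", name, "\"; available: ",
         paste(c(names(catalog), "reference_config"), collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", "partitions", paste0(name, ".json"),
                      package = "ptmnet")
  p <- if (nzchar(path)) {
    read_partition_json(path)
  } else {
    # fall back to the in-code definition (e.g. during development)
    do.call(ptm_partition, catalog[[name]])
  }
  attr(p, "fixture") <- name
  attr(p, "searchable") <- is_admissible(p) &&
    all(c("E1", "P2") %in% p$universe$labels)
  p
}

#' @rdname load_fixture
#' @export
fixture_names <- function() c(names(fixture_catalog()), "reference_config")

# Block definitions of every partition fixture.
fixture_catalog <- function() {
  list(
    fig1a = list(2, list("S1", "E1", c("P1", "E2"), "S2", "P2")),
    fig1b = list(2, list("S1", "E1", c("P1", "S2"), "E2", "P2")),
    fig1c = list(2, list(c("S1", "S2"), "E1", "P1", "E2", "P2")),
    fig1d = list(2, list("S1", "E1", "S2", "E2", c("P1", "P2"))),
    fig1e = list(1, list("S1", c("E1", "P1"))),
    fig1f = list(1, list(c("S1", "P1"), "E1")),
    fig1g = list(1, list(c("S1", "P1", "E1"))),
    fig2a = list(4, list(c("S1", "P2"), c("P1", "S2", "E1", "E4"),
                         c("S3", "P4"), c("P3", "S4", "E2", "E3"))),
    fig2b = list(10, list(
      c("P2", "S1"), c("P1", "S2", "E3", "E4"), "E1", "E2",
      c("P6", "S3"), c("P3", "P5", "S4", "S6"),
      c("P4", "S5", "E7", "E8"), c("P10", "S7"),
      c("P7", "P9", "S8", "S10"), c("P8", "S9"),
      "E5", "E6", "E9", "E10")),
    fig3A = list(2, list(c("S1", "P2", "E2"), c("P1", "E1"), "S2")),
    fig3B = list(2, list(c("S1", "P2"), c("E2", "P1", "E1", "S2"))),
    fig3C = list(2, list(c("S1", "P2", "E2"), c("P1", "E1", "S2")))
  )
}

# Regenerate the shipped JSON fixtures (used from a build script; exported
# data lives under inst/extdata/partitions/).
write_fixture_files <- function(dir) {
  catalog <- fixture_catalog()
  for (nm in names(catalog)) {
    p <- do.call(ptm_partition, catalog[[nm]])
    write_partition_json(p, file.path(dir, paste0(nm, ".json")))
  }
  invisible(names(catalog))
}

#' Load user-supplied kinetic parameter tables
#'
#' Reads an optional CSV/TSV of per-network rate constants and conserved
#' totals (e.g. transcribed from a published supplementary table; such
#' tables are not shipped with the package). Expected columns: `network`
#' (an identifier), then `a1..aN`, `d1..dN`, `k1..kN`, then any number of
#' `T1..TL` total-concentration columns (the input law's total may be `NA`
#' since it is swept).
#'
#' @param path file path; a missing file is reported as a skip, not an
#'   error.
#' @return A named list of [parameter_point()] objects, or `NULL` (with a
#'   message) when the file is absent.
#' @export
load_supplementary_parameters <- function(path) {
  if (!file.exists(path)) {
    message("optional parameter table not present: ", path)
    return(NULL)
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"network" %in% names(df)) {
    stop("parameter table must have a `network` column", call. = FALSE)
  }
  rate_cols <- grep("^[adk][0-9]+$", names(df), value = TRUE)
  tot_cols <- grep("^T[0-9]+$", names(df), value = TRUE)
  n <- length(grep("^a", rate_cols))
  if (n == 0L || length(rate_cols) != 3L * n) {
    stop("parameter table must have matching a*/d*/k* columns", call. = FALSE)
  }
  out <- list()
  for (r in seq_len(nrow(df))) {
    vals <- function(prefix) {
      v <- suppressWarnings(as.numeric(df[r, paste0(prefix, seq_len(n))]))
      if (anyNA(v)) {
        stop("malformed rate constants in row ", r, " (network ",
             df$network[r], ")", call. = FALSE)
      }
      v
    }
    totals <- as.numeric(df[r, tot_cols])
    out[[df$network[r]]] <- parameter_point(
      rate_constants(vals("a"), vals("d"), vals("k")), totals)
  }
  out
}
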