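#' Read assay tables with schema validation
#'
#' CSV contract: comma-separated, UTF-8, header row, '.' decimal; time in
#' seconds, formin in nM. Schemas: `"assembly"` (trace_id, formin_nM, time_s,
#' signal_au), `"filament"` (filament_id, time_s, length_um, optional
#' intensity_au), `"gel"` (gel_id, lane, formin_nM, band, intensity_au),
#' `"events"` (filament_id, t_pause_start_s, t_pause_end_s, t_burst_end_s,
#' burst_rate_sub_per_s, run_length_um).
#'
#' @param path CSV file path.
#' @param schema One of `"assembly"`, `"filament"`, `"gel"`, `"events"`.
#' @return Validated tibble.
#' @export
read_traces <- function(path, schema = c("assembly", "filament", "gel",
                                         "events")) {
  schema <- match.arg(schema)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_schema(df, schema, label = path)
}

schema_columns <- function(schema) {
  switch(schema,
    assembly = list(required = c("trace_id", "formin_nM", "time_s", "signal_au"),
                    numeric = c("formin_nM", "time_s", "signal_au"),
                    id = "trace_id", time = "time_s"),
    filament = list(required = c("filament_id", "time_s", "length_um"),
                    numeric = c("time_s", "length_um"),
                    id = "filament_id", time = "time_s"),
    gel = list(required = c("gel_id", "lane", "formin_nM", "band",
                            "intensity_au"),
               numeric = c("lane", "formin_nM", "intensity_au"),
               id = "gel_id", time = NULL),
    events = list(required = c("filament_id", "t_pause_start_s",
                               "t_pause_end_s", "t_burst_end_s",
                               "burst_rate_sub_per_s", "run_length_um"),
                  numeric = c("t_pause_start_s", "t_pause_end_s",
                              "t_burst_end_s", "burst_rate_sub_per_s",
                              "run_length_um"),
                  id = "filament_id", time = NULL)
  )
}

validate_schema <- function(df, schema, label = "data") {
  spec <- schema_columns(schema)
  missing <- setdiff(spec$required, names(df))
  if (length(missing)) {
    abort_input(label, ": missing column(s) ", paste(missing, collapse = ", "),
                " for schema '", schema, "'")
  }
  for (col in spec$numeric) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      abort_input(label, ": column '", col, "' is not numeric (first ",
                  "offending row: ", bad %||% 1L, ")")
    }
    if (anyNA(v)) {
      abort_input(label, ": column '", col, "' has missing values (first at ",
                  "row ", which(is.na(v))[1L], ")")
    }
  }
  if (!is.null(spec$time)) {
    for (id in unique(df[[spec$id]])) {
      tt <- df[[spec$time]][df[[spec$id]] == id]
      if (any(diff(tt) <= 0)) {
        abort_input(label, ": non-increasing time in ", spec$id, " '", id, "'")
      }
    }
  }
  tibble::as_tibble(df)
}

#' Write assay tables (inverse of [read_traces()])
#'
#' @param df Table to write (validated against the schema first).
#' @param path Output CSV path.
#' @inheritParams read_traces
#' @export
write_traces <- function(df, path, schema = c("assembly", "filament", "gel",
                                              "events")) {
  schema <- match.arg(schema)
  df <- validate_schema(df, schema, label = "data")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
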