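# Ingestion of connectome tables in the Codex CSV dialect and the
# semi-automatic DN naming rules.

NT_LEVELS <- c("ACH", "GABA", "GLUT", "DA", "SER", "OCT", "unknown")

#' Default Codex column-name map
#'
#' Column names drift between connectome snapshots, so the loader takes a
#' name map. The defaults correspond to the snapshot-630 table headers.
#'
#' @param ... name = "column" overrides for individual fields.
#' @return named list mapping canonical field names to file column names.
#' @export
codex_columns <- function(...) {
  defaults <- list(
    root_id = "root_id",
    super_class = "super_class",
    cell_type = "cell_type",
    hemibrain_type = "hemibrain_type",
    community_labels = "community_labels",
    side = "side",
    pre_root_id = "pre_root_id",
    post_root_id = "post_root_id",
    neuropil = "neuropil",
    syn_count = "syn_count",
    nt_type = "nt_type"
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) abort(paste0("unknown column-map field(s): ", toString(bad)))
  utils::modifyList(defaults, overrides)
}

normalise_nt <- function(x) {
  x <- first_upper(x)
  x[is.na(x) | !(x %in% setdiff(NT_LEVELS, "unknown"))] <- "unknown"
  x
}

check_ids <- function(ids, what) {
  ids <- trimws(as.character(ids))
  bad <- which(is.na(ids) | !grepl("^[0-9]+$", ids))
  if (length(bad)) {
    abort(sprintf("unparseable %s at row %d: '%s'", what, bad[1], ids[bad[1]]))
  }
  ids
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(unlist(cols), names(df))
  if (length(missing)) {
    abort(sprintf("file '%s' is missing required column(s): %s",
                  file, toString(missing)))
  }
}

#' Read Codex-dialect neuron and connection tables
#'
#' Reads the two core connectome tables (neurons and connections), maps
#' dialect column names through `col_map`, normalises neurotransmitter
#' strings to the fixed vocabulary (`ACH`, `GABA`, `GLUT`, `DA`, `SER`,
#' `OCT`, everything else `unknown`), and drops self-loop connection rows
#' (autapses) with a logged count. Root IDs are 64-bit integers that exceed
#' double precision, so they are carried as character strings throughout.
#'
#' @param neuron_table_path,connection_table_path CSV file paths.
#' @param col_map column-name map, see [codex_columns()].
#' @return list with tibbles `neurons` (`root_id`, `super_class`,
#'   `cell_type`, `hemibrain_type`, `community_labels`, `side`) and
#'   `connections` (`pre_root_id`, `post_root_id`, `neuropil`, `syn_count`,
#'   `nt_type`).
#' @export
read_codex_tables <- function(neuron_table_path, connection_table_path,
                              col_map = codex_columns()) {
  for (p in c(neuron_table_path, connection_table_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  neurons <- read_csv(neuron_table_path, col_types = cols(.default = col_character()),
                      progress = FALSE)
  require_columns(neurons, col_map[c("root_id", "super_class")], neuron_table_path)
  get_or_na <- function(df, col) {
    if (col %in% names(df)) df[[col]] else NA_character_
  }
  neurons <- tibble(
    root_id = check_ids(neurons[[col_map$root_id]], "root_id"),
    super_class = tolower(trimws(neurons[[col_map$super_class]])),
    cell_type = get_or_na(neurons, col_map$cell_type),
    hemibrain_type = get_or_na(neurons, col_map$hemibrain_type),
    community_labels = get_or_na(neurons, col_map$community_labels),
    side = tolower(get_or_na(neurons, col_map$side) %||% "unknown")
  )
  neurons$side[is.na(neurons$side) |
                 !(neurons$side %in% c("left", "right", "center"))] <- "unknown"
  if (anyDuplicated(neurons$root_id)) {
    abort("duplicated root_id in neuron table")
  }

  conn <- read_csv(connection_table_path, col_types = cols(.default = col_character()),
                   progress = FALSE)
  require_columns(conn,
                  col_map[c("pre_root_id", "post_root_id", "neuropil",
                            "syn_count", "nt_type")],
                  connection_table_path)
  syn <- suppressWarnings(as.numeric(conn[[col_map$syn_count]]))
  bad <- which(is.na(syn) | syn < 1 | syn != round(syn))
  if (length(bad)) {
    abort(sprintf("invalid syn_count at row %d: '%s'",
                  bad[1], conn[[col_map$syn_count]][bad[1]]))
  }
  connections <- tibble(
    pre_root_id = check_ids(conn[[col_map$pre_root_id]], "pre_root_id"),
    post_root_id = check_ids(conn[[col_map$post_root_id]], "post_root_id"),
    neuropil = trimws(conn[[col_map$neuropil]]),
    syn_count = as.integer(syn),
    nt_type = normalise_nt(conn[[col_map$nt_type]])
  )
  n_self <- sum(connections$pre_root_id == connections$post_root_id)
  if (n_self > 0) {
    inform(sprintf("dropped %d self-loop connection row(s)", n_self))
    connections <- filter(connections, .data$pre_root_id != .data$post_root_id)
  }
  inform(sprintf("loaded %d neurons and %d connection rows",
                 nrow(neurons), nrow(connections)))
  list(neurons = neurons, connections = connections)
}

#' Select descending neurons
#'
#' Returns the root IDs whose `super_class` is `"descending"`.
#'
#' @param neurons neuron tibble as returned by [read_codex_tables()].
#' @return character vector of DN root IDs (possibly empty).
#' @export
select_descending <- function(neurons) {
  ids <- neurons$root_id[neurons$super_class == "descending"]
  if (!length(ids)) inform("no neurons with super_class = descending")
  ids
}

#' Does a name follow the Namiki DN format?
#'
#' The Namiki driver-line naming scheme is `DN` + one lowercase letter +
#' exactly two digits (e.g. `"DNp16"`). The broader consensus cell-type
#' scheme (`DN` + one or more lowercase letters + one or more digits, e.g.
#' `"DNge078"`) is matched by [is_consensus_format()].
#'
#' @param name character vector.
#' @return logical vector.
#' @export
is_namiki_format <- function(name) {
  !is.na(name) & grepl("^DN[a-z][0-9]{2}$", name)
}

#' @rdname is_namiki_format
#' @export
is_consensus_format <- function(name) {
  !is.na(name) & grepl("^DN[a-z]+[0-9]+$", name)
}

#' Is a consensus cell type a GNG DN?
#'
#' DNs with somas in the gnathal ganglia (GNG) are recognised by the third
#' letter of their consensus cell type being `g` (e.g. `"DNge197"`). Names
#' not in consensus format return `FALSE` (with a note).
#'
#' @param consensus_name character vector of consensus cell types.
#' @return logical vector.
#' @export
is_gng_dn <- function(consensus_name) {
  ok <- is_consensus_format(consensus_name)
  if (any(!ok & !is.na(consensus_name) & nzchar(consensus_name))) {
    inform("is_gng_dn: some names are not in consensus format; returning FALSE for those")
  }
  ok & substr(consensus_name, 3, 3) == "g"
}

#' Default manual name overrides for special DNs
#'
#' The four MDN, two aDN1 and two aDN2 cells carry community labels rather
#' than usable cell-type attributes and are named manually by root ID.
#'
#' @return named character vector, names are root IDs, values DN names.
#' @export
default_dn_overrides <- function() {
  c(
    "720575940610236514" = "MDN",
    "720575940640331472" = "MDN",
    "720575940631082808" = "MDN",
    "720575940616026939" = "MDN",
    "720575940616185531" = "aDN1",
    "720575940624319124" = "aDN1",
    "720575940624220925" = "aDN2",
    "720575940629806974" = "aDN2"
  )
}

#' Assign DN names by the semi-automatic precedence rules
#'
#' Applies, in order: manual override; identical Namiki-format
#' `hemibrain_type` and `cell_type`; Namiki-format `hemibrain_type`;
#' Namiki-format `cell_type`; consensus-format `cell_type`; otherwise the
#' cell is marked as needing manual intervention. Conflicting Namiki names
#' in both attributes are also marked for manual intervention. Cells needing
#' manual intervention carry no `name`; `display_name` falls back to the
#' root ID so that downstream graph operations have total naming.
#'
#' @param neurons neuron tibble.
#' @param dn_ids character vector of DN root IDs (subset of `neurons$root_id`).
#' @param manual_overrides named character vector (root ID -> name); defaults
#'   to the eight special cells from [default_dn_overrides()].
#' @return tibble with `root_id`, `name`, `display_name`, `name_source`
#'   (`manual_special`, `namiki_both`, `namiki_hemibrain`, `namiki_celltype`,
#'   `consensus_celltype`, `needs_manual`) and `is_gng`.
#' @export
assign_dn_names <- function(neurons, dn_ids,
                            manual_overrides = default_dn_overrides()) {
  if (!all(dn_ids %in% neurons$root_id)) {
    abort("dn_ids must be a subset of neurons$root_id")
  }
  unused <- setdiff(names(manual_overrides), dn_ids)
  if (length(unused)) {
    warn(sprintf("%d manual override id(s) not among dn_ids; ignored", length(unused)))
  }
  df <- neurons[match(dn_ids, neurons$root_id), ]
  h <- df$hemibrain_type
  ct <- df$cell_type
  h_nam <- is_namiki_format(h)
  c_nam <- is_namiki_format(ct)
  c_cons <- is_consensus_format(ct)
  manual <- unname(manual_overrides[df$root_id])

  name_source <- case_when(
    !is.na(manual) ~ "manual_special",
    h_nam & c_nam & h == ct ~ "namiki_both",
    h_nam & c_nam ~ "needs_manual",
    h_nam ~ "namiki_hemibrain",
    c_nam ~ "namiki_celltype",
    c_cons ~ "consensus_celltype",
    TRUE ~ "needs_manual"
  )
  name <- case_when(
    name_source == "manual_special" ~ manual,
    name_source == "namiki_both" ~ h,
    name_source == "namiki_hemibrain" ~ h,
    name_source == "namiki_celltype" ~ ct,
    name_source == "consensus_celltype" ~ ct,
    TRUE ~ NA_character_
  )
  tibble(
    root_id = df$root_id,
    name = name,
    display_name = coalesce(name, df$root_id),
    name_source = name_source,
    is_gng = suppressMessages(is_gng_dn(ct))
  )
}

#' Write the DN name table
#'
#' @param assignments tibble from [assign_dn_names()].
#' @param path output TSV path.
#' @return the input, invisibly.
#' @export
write_dn_names <- function(assignments, path) {
  write_tsv(assignments[, c("root_id", "name", "name_source", "is_gng")], path)
  invisible(assignments)
}
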