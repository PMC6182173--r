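#' Default column dialect for interaction tables
#'
#' Maps the canonical field names onto the column names of an input table.
#' Override individual entries to read tables with other headers.
#'
#' @return Named list of column names.
#' @export
default_dialect <- function() {
  list(tf = "TF", cytokine = "Cytokine", species = "Species",
       assay = "Assay", activity = "Activity", pmid = "PMID")
}

#' Default free-text assay name mapping
#'
#' Maps free-text assay descriptions (lower case) onto the three fixed assay
#' categories: `chip`, `binding_in_vitro` and `functional` (chromatin
#' immunoprecipitation, in vitro binding such as EMSA/pull-down, and
#' functional assays such as reporters and knockdowns).
#'
#' @return Named character vector, names are surface forms.
#' @export
default_assay_map <- function() {
  c("chip" = "chip",
    "chip-seq" = "chip",
    "chip-qpcr" = "chip",
    "chromatin immunoprecipitation" = "chip",
    "emsa" = "binding_in_vitro",
    "gel shift" = "binding_in_vitro",
    "gel-shift" = "binding_in_vitro",
    "pull down" = "binding_in_vitro",
    "pull-down" = "binding_in_vitro",
    "in vitro binding" = "binding_in_vitro",
    "dnase footprinting" = "binding_in_vitro",
    "binding_in_vitro" = "binding_in_vitro",
    "functional" = "functional",
    "reporter" = "functional",
    "luciferase" = "functional",
    "knockdown" = "functional",
    "knockout" = "functional",
    "sirna" = "functional",
    "overexpression" = "functional")
}

assay_categories <- c("binding_in_vitro", "chip", "functional")
activity_levels <- c("activating", "repressing", "bifunctional", "unknown")

canonical_species <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("human", "mouse") | startsWith(x, "other:"),
         x, paste0("other:", x))
}

canonical_activity <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  out <- rep("unknown", length(x))
  out[x %in% c("activating", "activation", "activator")] <- "activating"
  out[x %in% c("repressing", "repression", "repressor")] <- "repressing"
  out[x %in% c("bifunctional", "both")] <- "bifunctional"
  out
}

#' Read and canonicalize a curated interaction table
#'
#' Reads a delimited table of curated TF-cytokine protein-DNA interactions
#' (PDIs), canonicalizes symbols (upper case, whitespace trimmed), maps
#' free-text assay names to the three assay categories, and merges duplicate
#' rows by (TF, cytokine, species): assay categories and article IDs are
#' unioned; conflicting annotated activities become `bifunctional`.
#' The evidence level of each merged record is derived with
#' [classify_evidence()].
#'
#' Rows with a blank TF or cytokine symbol, or with no recognisable assay,
#' are rejected with a warning; the count is stored in the `"rejected"`
#' attribute of the result.
#'
#' @param path Path to a TSV (or CSV, by extension) file.
#' @param dialect Column-name mapping, see [default_dialect()].
#' @param assay_map Free-text assay mapping, see [default_assay_map()].
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return A data frame of class `interaction_records` with columns
#'   `tf`, `cytokine`, `species`, `assays` (list), `activity`,
#'   `pmids` (list) and `evidence`.
#' @export
read_interaction_table <- function(path, dialect = default_dialect(),
                                   assay_map = default_assay_map(),
                                   sep = NULL) {
  if (!file.exists(path)) stop("interaction table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"")
  mandatory <- c("tf", "cytokine", "species", "assay")
  for (field in mandatory) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw))
      stop("missing mandatory column for field '", field, "': ",
           col %||% "<unmapped>")
  }
  if (nrow(raw) == 0) {
    warning("empty interaction table: ", path)
    return(interaction_records(data.frame()))
  }
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) as.character(raw[[col]])
    else rep(default, nrow(raw))
  }
  tf <- toupper(trimws(get_col("tf")))
  cytokine <- toupper(trimws(get_col("cytokine")))
  species <- canonical_species(get_col("species"))
  activity <- canonical_activity(get_col("activity"))
  pmid_raw <- get_col("pmid", "")
  assay_raw <- get_col("assay")

  names(assay_map) <- tolower(names(assay_map))
  unmapped <- character(0)
  assays <- lapply(assay_raw, function(a) {
    terms <- tolower(trimws(strsplit(ifelse(is.na(a), "", a), "[;,|]")[[1]]))
    terms <- terms[nzchar(terms)]
    hit <- terms %in% names(assay_map)
    if (any(!hit)) unmapped <<- c(unmapped, terms[!hit])
    sort(unique(unname(assay_map[terms[hit]])))
  })
  if (length(unmapped) > 0)
    warning("unrecognised assay terms ignored: ",
            paste(sort(unique(unmapped)), collapse = ", "))
  pmids <- lapply(pmid_raw, function(p) {
    ids <- trimws(strsplit(ifelse(is.na(p), "", p), "[;,|]")[[1]])
    sort(unique(ids[nzchar(ids)]))
  })

  bad <- !nzchar(tf) | !nzchar(cytokine) | tf == "NA" | cytokine == "NA" |
    lengths(assays) == 0
  if (any(bad))
    warning(sum(bad), " row(s) rejected (blank symbol or no mapped assay)")
  keep <- which(!bad)

  key <- paste(tf, cytokine, species, sep = "\r")[keep]
  groups <- split(keep, factor(key, levels = unique(key)))
  rec <- do.call(rbind, lapply(groups, function(idx) {
    acts <- setdiff(unique(activity[idx]), "unknown")
    act <- if (length(acts) == 0) "unknown"
    else if (length(acts) == 1) acts
    else "bifunctional"
    data.frame(tf = tf[idx[1]], cytokine = cytokine[idx[1]],
               species = species[idx[1]], activity = act,
               stringsAsFactors = FALSE)
  }))
  rec$assays <- unname(lapply(groups, function(idx)
    sort(unique(unlist(assays[idx])))))
  rec$pmids <- unname(lapply(groups, function(idx)
    sort(unique(unlist(pmids[idx])))))
  rec$evidence <- vapply(rec$assays, classify_evidence, character(1))
  rownames(rec) <- NULL
  out <- interaction_records(rec[c("tf", "cytokine", "species", "assays",
                                   "activity", "pmids", "evidence")])
  attr(out, "rejected") <- sum(bad)
  out
}

interaction_records <- function(df) {
  if (nrow(df) == 0) {
    df <- data.frame(tf = character(0), cytokine = character(0),
                     species = character(0), activity = character(0),
                     evidence = character(0), stringsAsFactors = FALSE)
    df$assays <- list()
    df$pmids <- list()
  }
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Classify the evidence level of a PDI
#'
#' A PDI is `high` evidence when it was detected by a functional assay and
#' by at least one assay measuring direct binding (`chip` or
#' `binding_in_vitro`); PDIs detected by only one type of assay are `low`
#' evidence. Binding-only combinations without a functional assay are
#' also `low`.
#'
#' @param assay_set Character vector, a non-empty subset of
#'   `c("binding_in_vitro", "chip", "functional")`.
#' @return `"high"` or `"low"`.
#' @export
classify_evidence <- function(assay_set) {
  if (length(assay_set) == 0) stop("assay set must be non-empty")
  if (!all(assay_set %in% assay_categories))
    stop("unknown assay categories: ",
         paste(setdiff(assay_set, assay_categories), collapse = ", "))
  if ("functional" %in% assay_set &&
      any(c("chip", "binding_in_vitro") %in% assay_set)) "high" else "low"
}

#' Write the canonical six-column interaction table
#'
#' Emits a UTF-8 TSV with columns TF, Cytokine, Species, Assay, Activity,
#' PMID; multi-valued fields are `;`-joined. Reading the file back with
#' [read_interaction_table()] reproduces the canonical records.
#'
#' @param records An `interaction_records` data frame or a [cytokine_grn()].
#' @param path Output path.
#' @export
write_interaction_table <- function(records, path) {
  if (inherits(records, "cytokine_grn")) records <- records$records
  out <- data.frame(
    TF = records$tf, Cytokine = records$cytokine, Species = records$species,
    Assay = vapply(records$assays, paste, character(1), collapse = ";"),
    Activity = records$activity,
    PMID = vapply(records$pmids, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a bipartite cytokine GRN from interaction records
#'
#' Collects the records of one species into a bipartite network object with
#' per-node degree maps. TF degree counts distinct cytokine targets;
#' cytokine degree counts distinct interacting TFs (citations do not add
#' degree).
#'
#' @param records An `interaction_records` data frame.
#' @param species Optional species filter (e.g. `"human"`).
#' @return An object of class `cytokine_grn`: a list with elements
#'   `species`, `records`, `tf_degree` and `cytokine_degree`.
#' @export
cytokine_grn <- function(records, species = NULL) {
  if (!is.null(species)) {
    records <- records[records$species == species, , drop = FALSE]
  } else {
    sp <- unique(records$species)
    species <- if (length(sp) == 1) sp else NA_character_
  }
  records <- records[!duplicated(paste(records$tf, records$cytokine,
                                       sep = "\r")), , drop = FALSE]
  rownames(records) <- NULL
  tf_degree <- sort(table(records$tf), decreasing = TRUE)
  cytokine_degree <- sort(table(records$cytokine), decreasing = TRUE)
  structure(list(
    species = species,
    records = records,
    tf_degree = setNames(as.integer(tf_degree), names(tf_degree)),
    cytokine_degree = setNames(as.integer(cytokine_degree),
                               names(cytokine_degree))),
    class = "cytokine_grn")
}

#' @export
print.cytokine_grn <- function(x, ...) {
  cat("Cytokine GRN (", x$species %||% "mixed", "): ",
      nrow(x$records), " PDIs, ", length(x$tf_degree), " TFs, ",
      length(x$cytokine_degree), " cytokines\n", sep = "")
  invisible(x)
}

grn_pairs <- function(grn) paste(grn$records$tf, grn$records$cytokine,
                                 sep = "\r")

#' Minimal top-degree node fraction covering a share of the PDIs
#'
#' Ranks nodes on one side of the bipartite network by degree (ties broken
#' lexicographically by symbol) and returns `k/N`, where `k` is the smallest
#' number of top nodes whose summed degrees strictly exceed
#' `coverage` times the total number of PDIs.
#'
#' @param grn A [cytokine_grn()].
#' @param side `"tf"` or `"cytokine"`.
#' @param coverage Fraction of PDIs to exceed, in (0, 1).
#' @return The node fraction `k/N`.
#' @export
degree_rank_coverage <- function(grn, side = c("tf", "cytokine"),
                                 coverage = 0.5) {
  side <- match.arg(side)
  stopifnot(coverage > 0, coverage < 1)
  deg <- if (side == "tf") grn$tf_degree else grn$cytokine_degree
  if (length(deg) == 0) stop("empty network")
  ord <- order(-deg, names(deg))
  cs <- cumsum(deg[ord])
  total <- sum(deg)
  k <- unname(which(cs > coverage * total)[1])
  if (is.na(k)) k <- length(deg)
  k / length(deg)
}

#' Overlap between two species' cytokine GRNs
#'
#' Compares (TF, cytokine) pairs after mapping the second network's symbols
#' through an ortholog map (default: case-insensitive symbol identity;
#' symbols absent from the map are kept as-is and can only match by
#' identity, so genes without a counterpart remain species-specific).
#'
#' @param grn_a,grn_b Two [cytokine_grn()] objects.
#' @param ortholog_map Optional named character vector mapping `grn_b`
#'   symbols onto `grn_a` symbols.
#' @return A list of class `species_overlap` with `shared_pairs` (data
#'   frame), `frac_specific_a` and `frac_specific_b`.
#' @export
species_overlap <- function(grn_a, grn_b, ortholog_map = NULL) {
  stopifnot(nrow(grn_a$records) > 0, nrow(grn_b$records) > 0)
  map_sym <- function(s) {
    s <- toupper(s)
    if (is.null(ortholog_map)) return(s)
    names(ortholog_map) <- toupper(names(ortholog_map))
    hit <- s %in% names(ortholog_map)
    s[hit] <- toupper(unname(ortholog_map[s[hit]]))
    s
  }
  key_a <- paste(toupper(grn_a$records$tf), toupper(grn_a$records$cytokine),
                 sep = "\r")
  key_b <- paste(map_sym(grn_b$records$tf), map_sym(grn_b$records$cytokine),
                 sep = "\r")
  shared <- intersect(key_a, key_b)
  parts <- do.call(rbind, strsplit(shared, "\r"))
  structure(list(
    shared_pairs = data.frame(
      tf = if (length(shared)) parts[, 1] else character(0),
      cytokine = if (length(shared)) parts[, 2] else character(0),
      stringsAsFactors = FALSE),
    frac_specific_a = 1 - length(shared) / length(key_a),
    frac_specific_b = 1 - length(shared) / length(key_b)),
    class = "species_overlap")
}

#' Fraction of activity-annotated PDIs with a given regulatory activity
#'
#' Computed over records whose regulatory activity is annotated
#' (`unknown` excluded from the denominator).
#'
#' @param grn A [cytokine_grn()].
#' @param activity One of `"activating"`, `"repressing"`, `"bifunctional"`.
#' @return Fraction in `[0, 1]`.
#' @export
activity_fraction <- function(grn, activity = "activating") {
  stopifnot(activity %in% setdiff(activity_levels, "unknown"))
  annotated <- grn$records$activity != "unknown"
  if (!any(annotated)) stop("no PDIs with annotated regulatory activity")
  mean(grn$records$activity[annotated] == activity)
}
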