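#' Closed vocabularies for entity classes and biological processes
#'
#' The pipeline recognises five entity classes and ten metabolic-process
#' labels. Process membership drives subnetwork construction; the class
#' drives the bipartite constraint (regulators on one side, metabolic
#' genes, proteins and metabolites on the other) and the Cytoscape node
#' shapes (regulators are circles, genes/proteins squares, metabolites
#' triangles).
#'
#' @return character vector of allowed labels.
#' @export
process_vocabulary <- function() c(
  "lipid", "calvin_cycle", "nitrogen", "photosynthesis", "photorespiration",
  "oppp", "citrate_glyoxylate", "sucrose_starch", "amino_acid", "chlorophyll")

#' @rdname process_vocabulary
#' @export
entity_classes <- function() c("TF", "TR", "metabolic_gene", "metabolite", "protein")

is_regulator_class <- function(cls) cls %in% c("TF", "TR")

class_shape <- function(cls) {
  out <- rep(NA_character_, length(cls))
  out[cls %in% c("TF", "TR")] <- "circle"
  out[cls %in% c("metabolic_gene", "protein")] <- "square"
  out[cls == "metabolite"] <- "triangle"
  out
}

#' Entity annotation table
#'
#' Validates a data frame of entity annotations: `id`, `class` (one of
#' [entity_classes()]), `family` (regulator family label, required for
#' TF/TR, disallowed for metabolites) and `processes` (subset of
#' [process_vocabulary()]).
#'
#' @param df data frame with columns `id`, `class`, optional `family`,
#'   and `processes` either as a list column or as strings delimited by
#'   `";"` or `"|"`.
#' @return a data frame of class `lagnet_annotations` with a list column
#'   `processes`.
#' @seealso [read_annotations()]
#' @export
annotations <- function(df) {
  need <- c("id", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("missing column(s): ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop_("duplicate entity id in annotations")
  bad <- setdiff(unique(df$class), entity_classes())
  if (length(bad)) stop_("unknown entity class: ", paste(bad, collapse = ", "))
  if (is.null(df$family)) df$family <- NA_character_
  df$family[!is.na(df$family) & !nzchar(df$family)] <- NA_character_
  if (any(is_regulator_class(df$class) & is.na(df$family)))
    stop_("regulators (TF/TR) must carry a family label")
  if (any(df$class == "metabolite" & !is.na(df$family)))
    stop_("metabolites carry no family label")
  pr <- df$processes %||% vector("list", nrow(df))
  if (!is.list(pr))
    pr <- strsplit(ifelse(is.na(pr), "", as.character(pr)), "[;|]")
  pr <- lapply(pr, function(p) {
    p <- trimws(p[nzchar(trimws(p))])
    unk <- setdiff(p, process_vocabulary())
    if (length(unk)) stop_("unknown process label: ", paste(unk, collapse = ", "))
    p
  })
  out <- data.frame(id = df$id, class = df$class, family = df$family,
                    stringsAsFactors = FALSE)
  out$processes <- pr
  class(out) <- c("lagnet_annotations", "data.frame")
  out
}

#' Read or write an entity annotation table
#'
#' Files have columns `id`, `class`, `family`, `processes`, the latter
#' delimited by `";"` or `"|"` within the field. Validation is strict:
#' unknown classes or process labels are errors.
#'
#' @param path file to read or write; delimiter follows the extension.
#' @return `read_annotations()` returns a `lagnet_annotations` table.
#' @export
read_annotations <- function(path) {
  annotations(read_delim_table(path))
}

#' @rdname read_annotations
#' @param ann a `lagnet_annotations` table.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "lagnet_annotations"))
  out <- data.frame(id = ann$id, class = ann$class, family = ann$family,
                    processes = vapply(ann$processes, paste, "", collapse = ";"))
  write_delim_table(out, path)
}

## named lookup helpers
ann_class <- function(ann, ids) {
  i <- match(ids, ann$id)
  if (anyNA(i)) stop_("unannotated node: ", paste(ids[is.na(i)], collapse = ", "))
  ann$class[i]
}
ann_processes <- function(ann, ids) {
  i <- match(ids, ann$id)
  out <- vector("list", length(ids))
  out[!is.na(i)] <- ann$processes[i[!is.na(i)]]
  out
}
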