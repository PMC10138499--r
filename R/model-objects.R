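#' @title Model object constructors
#' @description
#' The model has four addressable kinds: entity objects (one biological
#' entity, keyed by type + primary identifier), identifier objects
#' (type/title/value records shareable across entities), data objects
#' (non-identifier metadata with a dataset source label) and relations
#' (labeled directed property-carrying edges). Every object's unique ID
#' is derived from its content via [bg_id()].
#' @name model-objects
NULL

#' Base entity-relation vocabulary
#'
#' The six base labels for entity-to-entity relations. The vocabulary is
#' open: any other nonempty label is accepted but flagged as an extension
#' label by [bg_is_base_label()].
#'
#' @format Character vector of six labels.
#' @export
BG_BASE_RELATIONS <- c("IS", "IS_INSTANCE", "IS_VARIANT", "FROM",
                       "CONTAINS", "RELATED_WITH")

#' Structural relation labels linking entities to identifier/data nodes
#' @rdname BG_BASE_RELATIONS
#' @export
BG_STRUCTURAL_RELATIONS <- c("HAS_ID", "HAS_DATA")

bg_trim <- function(x) gsub("^\\s+|\\s+$", "", x)

stop_validation <- function(fmt, ...) {
  stop(structure(
    class = c("bg_validation_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_nonempty <- function(value, field) {
  if (length(value) != 1L || is.na(value) || !nzchar(bg_trim(as.character(value))))
    stop_validation("field '%s' must be a nonempty string", field)
  invisible(TRUE)
}

is_scalar_value <- function(v) {
  length(v) == 1L && !is.na(v) &&
    (is.character(v) || is.numeric(v) || is.logical(v))
}

#' Normalize a relation label
#'
#' Upper-cases and converts runs of spaces/hyphens to underscores so that
#' "HAS ID" and "has_id" share one canonical spelling.
#'
#' @param label Character scalar.
#' @return Canonical label string.
#' @export
bg_normalize_label <- function(label) {
  check_nonempty(label, "label")
  gsub("[ -]+", "_", toupper(bg_trim(label)))
}

#' Is a relation label part of the base vocabulary?
#'
#' @param label Character scalar (normalized or not).
#' @return TRUE for the six base entity-relation labels, FALSE otherwise.
#' @export
bg_is_base_label <- function(label) {
  bg_normalize_label(label) %in% BG_BASE_RELATIONS
}

#' Construct an entity object
#'
#' An entity object represents a single biological (or contextual) entity,
#' uniquely determined by its lowercase-normalized type and its primary
#' identifier — the one identifier chosen to name the entity across
#' datasets (e.g. gene symbol, UniProt accession).
#'
#' @param entity_type Entity type label, e.g. "gene", "protein", "disease",
#'   "antigen", "epitope", "organism". Lowercased on construction.
#' @param primary_identifier Primary identifier string; trimmed.
#' @return A `bg_entity` object.
#' @examples
#' bg_entity("gene", "CDKN1A")
#' @export
bg_entity <- function(entity_type, primary_identifier) {
  check_nonempty(entity_type, "entity_type")
  check_nonempty(primary_identifier, "primary_identifier")
  structure(
    list(entity_type = tolower(bg_trim(entity_type)),
         primary_identifier = bg_trim(primary_identifier)),
    class = c("bg_entity", "bg_object")
  )
}

#' Construct an identifier object
#'
#' Identifier objects record any identifier an entity carries and are
#' shareable among entities (attached via HAS_ID edges). The kind of an
#' identifier is one of three: a name, a URL, or a generic identifier.
#'
#' @param id_type One of "name", "url", "id".
#' @param title Meaning of the identifier, e.g. "gene name", "NCBI ID".
#' @param value The identifier string itself.
#' @return A `bg_identifier` object.
#' @examples
#' bg_identifier("id", "UniProt ID", "P38936")
#' @export
bg_identifier <- function(id_type, title, value) {
  check_nonempty(id_type, "id_type")
  id_type <- tolower(bg_trim(id_type))
  if (!id_type %in% c("name", "url", "id"))
    stop_validation("id_type '%s' unknown; allowed kinds: name, url, id", id_type)
  check_nonempty(title, "title")
  check_nonempty(value, "value")
  structure(
    list(id_type = id_type, title = bg_trim(title), value = bg_trim(value)),
    class = c("bg_identifier", "bg_object")
  )
}

#' Construct a data object
#'
#' Data objects bundle non-identifier metadata (disorder content,
#' chromosome location, annotations, ...) with the label of the dataset
#' they came from, so values remain traceable to their source. Attached to
#' entities via HAS_DATA edges. Payload key order is irrelevant to the
#' object's identity.
#'
#' @param source_label Name of the originating dataset, e.g. "disprot".
#' @param payload Named list of scalar values (string, number or boolean).
#' @return A `bg_data` object.
#' @examples
#' bg_data("disprot", list(disorder_content = 0.9))
#' @export
bg_data <- function(source_label, payload) {
  check_nonempty(source_label, "source_label")
  if (!is.list(payload) || length(payload) == 0L)
    stop_validation("payload must be a nonempty named list")
  keys <- names(payload)
  if (is.null(keys) || any(!nzchar(keys)) || anyDuplicated(keys))
    stop_validation("payload keys must be unique nonempty strings")
  for (k in keys) {
    if (!is_scalar_value(payload[[k]]))
      stop_validation("payload value for key '%s' must be a scalar string, number or boolean", k)
  }
  structure(
    list(source_label = bg_trim(source_label), payload = payload[order(keys)]),
    class = c("bg_data", "bg_object")
  )
}

#' Construct a relation
#'
#' Relations are labeled directed edges between stored objects, optionally
#' carrying properties (e.g. a gene-disease association score). HAS_ID
#' edges connect entities to identifier objects, HAS_DATA edges connect
#' entities to data objects, and entity-relation labels (see
#' [BG_BASE_RELATIONS]) connect entities to entities. Endpoint-kind
#' constraints are enforced when the relation is stored. Self-relations
#' are rejected: no base label admits them.
#'
#' @param label Relation label; normalized via [bg_normalize_label()].
#' @param source_id,target_id Object IDs of the endpoints (64-char hex).
#' @param props Named list of scalar edge properties; may be empty.
#' @return A `bg_relation` object.
#' @examples
#' g <- bg_id(bg_entity("gene", "CDKN1A"))
#' d <- bg_id(bg_entity("disease", "C0038356"))
#' bg_relation("RELATED_WITH", g, d, list(score = 0.9))
#' @export
bg_relation <- function(label, source_id, target_id, props = list()) {
  label <- bg_normalize_label(label)
  check_id_syntax(source_id, "source_id")
  check_id_syntax(target_id, "target_id")
  if (identical(source_id, target_id))
    stop_validation("self-relation not allowed for label '%s'", label)
  if (!is.list(props))
    stop_validation("props must be a (possibly empty) named list")
  keys <- names(props)
  if (length(props) > 0L) {
    if (is.null(keys) || any(!nzchar(keys)) || anyDuplicated(keys))
      stop_validation("props keys must be unique nonempty strings")
    for (k in keys) {
      if (!is_scalar_value(props[[k]]))
        stop_validation("props value for key '%s' must be a scalar", k)
    }
    props <- props[order(keys)]
  }
  structure(
    list(label = label, source_id = source_id, target_id = target_id,
         props = props),
    class = c("bg_relation", "bg_object")
  )
}

check_id_syntax <- function(id, field) {
  if (length(id) != 1L || !is.character(id) || !grepl("^[0-9a-f]{64}$", id))
    stop_validation("field '%s' must be a 64-character lowercase hex object ID", field)
  invisible(TRUE)
}

#' Kind tag of a model object
#' @param object A model object.
#' @return One of "entity", "identifier", "data", "relation".
#' @export
bg_kind <- function(object) {
  if (inherits(object, "bg_entity")) return("entity")
  if (inherits(object, "bg_identifier")) return("identifier")
  if (inherits(object, "bg_data")) return("data")
  if (inherits(object, "bg_relation")) return("relation")
  stop_validation("not a model object")
}

#' @export
print.bg_entity <- function(x, ...) {
  cat(sprintf("<entity %s:%s>\n", x$entity_type, x$primary_identifier))
  invisible(x)
}

#' @export
print.bg_identifier <- function(x, ...) {
  cat(sprintf("<identifier [%s] %s = %s>\n", x$id_type, x$title, x$value))
  invisible(x)
}

#' @export
print.bg_data <- function(x, ...) {
  cat(sprintf("<data source=%s {%s}>\n", x$source_label,
              paste(names(x$payload), collapse = ", ")))
  invisible(x)
}

#' @export
print.bg_relation <- function(x, ...) {
  cat(sprintf("<relation %s %s -> %s%s>\n", x$label,
              substr(x$source_id, 1, 8), substr(x$target_id, 1, 8),
              if (length(x$props)) paste0(" {", paste(names(x$props), collapse = ", "), "}") else ""))
  invisible(x)
}
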