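#' Read and write annotations as COCO-style JSON
#'
#' Annotations are exchanged in the COCO convention: a top-level object with
#' \code{images}, \code{categories} and \code{annotations}, each annotation
#' holding \code{bbox = [x, y, width, height]} and a \code{category_id}.
#' Only the fields the toolkit consumes are written.
#'
#' @param ann An \code{\link{annotation_set}}.
#' @param path File path.
#' @param image_id Image identifier to stamp on each annotation.
#' @param categories Optional character vector of category names (index =
#'   category id).
#' @return \code{read_coco_annotations()}: an \code{annotation_set};
#'   \code{write_coco_annotations()}: \code{path}, invisibly.
#' @export
write_coco_annotations <- function(ann, path, image_id = 1L, categories = NULL) {
  cb <- bbox_to_coco(as_bbox(as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")])))
  cats <- if (is.null(categories)) {
    ids <- sort(unique(ann$class_id))
    lapply(ids, function(i) list(id = i, name = paste0("class_", i)))
  } else {
    lapply(seq_along(categories), function(i) list(id = i, name = categories[i]))
  }
  obj <- list(
    images = list(list(id = image_id)),
    categories = cats,
    annotations = lapply(seq_len(nrow(ann)), function(i) {
      list(id = i, image_id = image_id, category_id = ann$class_id[i],
           bbox = as.numeric(cb[i, ]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_annotations
#' @export
read_coco_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  anns <- obj$annotations
  if (!length(anns)) {
    return(annotation_set(matrix(numeric(0), 0, 4), integer(0)))
  }
  m <- t(vapply(anns, function(a) as.numeric(unlist(a$bbox)), numeric(4)))
  cls <- vapply(anns, function(a) as.integer(a$category_id), integer(1))
  annotation_set(coco_to_bbox(m), cls)
}

#' Read and write detections as COCO-style JSON
#'
#' Detections are written as a JSON array of result objects, COCO-results
#' style, each with \code{bbox = [x, y, width, height]},
#' \code{category_id}, \code{score}, and additionally the full per-class
#' probability vector under \code{probs} so suppression and reporting can be
#' replayed from file. On read, objects lacking \code{probs} are expanded to
#' a probability vector that puts \code{score} on \code{category_id} and
#' spreads the remainder uniformly.
#'
#' @param dets A \code{\link{detections}} object.
#' @param path File path.
#' @param n_classes Class count used when reconstructing probability
#'   vectors from bare scores (default: the largest category id seen).
#' @return \code{read_detections_json()}: a \code{detections} object;
#'   \code{write_detections_json()}: \code{path}, invisibly.
#' @export
write_detections_json <- function(dets, path) {
  stopifnot(inherits(dets, "detections"))
  cb <- bbox_to_coco(dets$boxes)
  obj <- lapply(seq_len(n_detections(dets)), function(i) {
    list(bbox = as.numeric(cb[i, ]), category_id = dets$class_id[i],
         score = dets$score[i], probs = as.numeric(dets$probs[i, ]))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections_json
#' @export
read_detections_json <- function(path, n_classes = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(obj)) {
    k <- if (is.null(n_classes)) 1L else n_classes
    return(detections(matrix(numeric(0), 0, 4), matrix(numeric(0), 0, k)))
  }
  m <- t(vapply(obj, function(d) as.numeric(unlist(d$bbox)), numeric(4)))
  has_probs <- !is.null(obj[[1L]]$probs)
  if (has_probs) {
    probs <- do.call(rbind, lapply(obj, function(d) as.numeric(unlist(d$probs))))
  } else {
    cls <- vapply(obj, function(d) as.integer(d$category_id), integer(1))
    sc <- vapply(obj, function(d) as.numeric(d$score), numeric(1))
    k <- if (is.null(n_classes)) max(cls) else n_classes
    probs <- matrix(0, length(obj), k)
    for (i in seq_along(obj)) {
      probs[i, ] <- if (k > 1L) (1 - sc[i]) / (k - 1L) else 0
      probs[i, cls[i]] <- sc[i]
    }
  }
  detections(coco_to_bbox(m), probs)
}

#' Write a sample-assignment table as augmented COCO-style JSON
#'
#' Serializes \code{\link{assign_samples}} output: each record carries the
#' candidate \code{bbox}, \code{score}, \code{overlap}, \code{stage},
#' \code{label} and \code{weight} fields, for consumption by an external
#' trainer.
#'
#' @param assignment A \code{"sample_assignment"} data frame.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_assignments_json <- function(assignment, path) {
  cb <- bbox_to_coco(as_bbox(as.matrix(
    assignment[, c("x_min", "y_min", "x_max", "y_max")])))
  obj <- lapply(seq_len(nrow(assignment)), function(i) {
    list(bbox = as.numeric(cb[i, ]), score = assignment$score[i],
         overlap = assignment$overlap[i], stage = assignment$stage[i],
         label = as.character(assignment$label[i]),
         weight = assignment$weight[i])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a threshold configuration
#'
#' Reads a structured config (JSON always; YAML when the yaml package is
#' available) and builds the corresponding \code{\link{stage_plan}}.
#' Recognized keys: \code{phi1}, \code{rho}, \code{n_stages},
#' \code{phi_ignore}; missing keys fall back to the package defaults
#' (0.5, 0.1, 3, 0.1).
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{stage_plan}.
#' @export
read_stage_plan <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(phi1 = 0.5, rho = 0.1, n_stages = 3L, phi_ignore = 0.1)
  args <- utils::modifyList(defaults, cfg[intersect(names(cfg), names(defaults))])
  do.call(stage_plan, args)
}
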