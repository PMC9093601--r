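# End-to-end cohort pipelines: the cohort-specific pseudo-atlas tractography
# method (a template subject's recipe-derived ROIs propagated to every other
# subject by affine FA registration, optionally after ACPC alignment) and
# the atlas-label comparator (per-tract metrics under a warped label
# volume).

#' Fit tensors and derive scalar maps for one subject
#'
#' The brain mask is taken from the estimated non-weighted signal (mean b0
#' above 5 percent of its maximum).
#'
#' @param dwi a [dwi_volume()].
#' @return list with `field`, `maps` (FA/MD/L1/RD), `mask`.
#' @export
subject_maps <- function(dwi) {
  b0 <- dwi$data[, , , dwi$gtab$bvals == 0, drop = FALSE]
  mb0 <- apply(b0, 1:3, mean)
  mask <- scalar_map((mb0 > 0.05 * max(mb0)) * 1, dwi$affine, "mask")
  field <- fit_tensor(dwi, mask)
  list(field = field, maps = scalar_maps(field), mask = mask)
}

# resample a reference geometry's structure masks through a rigid transform
transform_reference <- function(ref, transform) {
  W <- grid_world_coords(ref$shape, ref$affine)
  src <- apply_transform(W, solve(transform$matrix))
  structures <- lapply(ref$structures, function(m) {
    array(nearest_sample(m * 1, world_to_voxel(src, ref$affine),
                         fill = 0) > 0, ref$shape)
  })
  reference_geometry(ref$shape, ref$affine, structures)
}

#' Run the cohort-specific pseudo-atlas tractography method
#'
#' One subject serves as the template: its recipe gates are resolved
#' against its own reference structures (standing in for the rater's
#' manually placed ROIs). For every other subject the template FA map is
#' affinely registered to the subject FA map and the gates are propagated
#' through the recovered transform before streamline selection. With
#' `acpc = TRUE` all subjects (template included) are first rigidly
#' realigned from their ACPC landmarks, which removes inter-subject pose
#' variability before registration.
#'
#' @param subjects list of subjects from [generate_cohort()] (each a list
#'   with `dwi`, `truth`, `id`); for real data, equivalently structured
#'   inputs with landmark and structure masks.
#' @param recipes list of [tract_recipe()]s to extract.
#' @param template_index which subject is the template (default 1).
#' @param acpc rigidly ACPC-align all subjects first (default FALSE).
#' @param params [tracking_params()] for whole-brain tractography.
#' @param register use affine FA registration for gate propagation
#'   (default TRUE; FALSE propagates with the identity, which is only
#'   sensible for jitter-free cohorts).
#' @return list with `metrics` (long data.frame: one row per tract
#'   instance and per bilateral average), `generated` / `attempted`
#'   counts, `success_rate`, and per-subject `ei` when ventricle masks are
#'   present.
#' @export
run_pseudo_atlas <- function(subjects, recipes, template_index = 1L,
                             acpc = FALSE, params = tracking_params(),
                             register = TRUE) {
  stopifnot(length(subjects) >= 1L)
  prep <- lapply(subjects, function(s) {
    sm <- subject_maps(s$dwi)
    tg <- track_whole_brain(sm$field, sm$maps$FA, params)
    tr_acpc <- if (acpc) acpc_align(s$truth$landmarks) else
      spatial_transform(diag(4), "rigid")
    if (acpc) {
      sm$maps <- lapply(sm$maps, resample_map, transform = tr_acpc)
      tg <- transform_tractogram(tg, tr_acpc$matrix)
    }
    list(maps = sm$maps, tractogram = tg, acpc = tr_acpc, id = s$id)
  })
  tpl <- subjects[[template_index]]
  tpl_ref <- phantom_reference(tpl$truth)
  if (acpc) {
    tpl_ref <- transform_reference(tpl_ref, prep[[template_index]]$acpc)
  }
  tpl_fa <- prep[[template_index]]$maps$FA
  rows <- list()
  for (i in seq_along(subjects)) {
    p <- prep[[i]]
    if (i == template_index || !register) {
      tr <- spatial_transform(diag(4), "affine")
    } else {
      tr <- register_affine(tpl_fa, p$maps$FA)
    }
    for (rec in recipes) {
      sides <- if (rec$laterality == "midline") "n/a" else
        c("left", "right")
      for (sd in sides) {
        gates <- resolve_gates(rec, tpl_ref, side = sd)
        gates <- propagate_rois(gates, tr, dim(p$maps$FA$data),
                                p$maps$FA$affine)
        sel <- select_tract(p$tractogram, gates, p$maps$FA$affine)
        rows[[length(rows) + 1L]] <-
          tract_metrics(sel$streamlines, p$maps, subject = p$id,
                        tract = rec$tract,
                        side = if (sd == "n/a") "midline" else sd,
                        method = "pseudo_atlas")
      }
    }
  }
  metrics <- do.call(rbind, c(rows, make.row.names = FALSE))
  metrics$single_side <- FALSE
  metrics <- rbind(metrics, bilateral_rows(metrics))
  attempted <- attempted_count(recipes, length(subjects))
  generated <- sum(metrics$generated[metrics$side != "both"])
  list(metrics = metrics, attempted = attempted, generated = generated,
       success_rate = success_rate(generated, attempted))
}

# append side = "both" bilateral averages (and a whole-callosum "CC" row
# averaging gCC and bCC when both midline recipes are present)
bilateral_rows <- function(metrics) {
  out <- list()
  for (subj in unique(metrics$subject)) {
    sm <- metrics[metrics$subject == subj, ]
    for (tr in unique(sm$tract)) {
      st <- sm[sm$tract == tr, ]
      if (all(c("left", "right") %in% st$side)) {
        out[[length(out) + 1L]] <-
          bilateral_average(st[st$side == "left", ][1, ],
                            st[st$side == "right", ][1, ])
      }
    }
    if (all(c("gCC", "bCC") %in% sm$tract)) {
      g <- sm[sm$tract == "gCC", ][1, ]
      b <- sm[sm$tract == "bCC", ][1, ]
      cc <- g
      cc$tract <- "CC"
      cc$side <- "both"
      cc$single_side <- FALSE
      cols <- c("FA", "MD", "L1", "RD")
      if (g$generated && b$generated) {
        cc[cols] <- (g[cols] + b[cols]) / 2
        cc$n_streamlines <- g$n_streamlines + b$n_streamlines
      } else if (g$generated || b$generated) {
        src <- if (g$generated) g else b
        cc[cols] <- src[cols]
        cc$generated <- TRUE
      } else {
        cc$generated <- FALSE
      }
      out[[length(out) + 1L]] <- cc
    }
  }
  if (!length(out)) return(metrics[0, ])
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  if (!"single_side" %in% names(out)) out$single_side <- FALSE
  out
}

#' Run the atlas-label comparator over a cohort
#'
#' Extracts per-tract mean metrics under a label volume for every subject.
#' By default each subject's labels come from `atlas_builder(truth)`,
#' which for phantom work is the deliberately mismatched atlas
#' ([mismatched_atlas()]).
#'
#' @param subjects list of subjects.
#' @param atlas_builder function(truth) -> [atlas_labels()].
#' @param transform_builder function(subject) -> `spatial_transform`
#'   (atlas -> subject world; identity by default).
#' @return long data.frame of per-subject per-tract metrics, with
#'   bilateral (`side = "both"`) averages for paired labels (suffixes
#'   `_left` / `_right`) merged under the base tract name.
#' @export
run_atlas_method <- function(subjects,
                             atlas_builder = mismatched_atlas,
                             transform_builder = NULL) {
  rows <- list()
  for (s in subjects) {
    sm <- subject_maps(s$dwi)
    atlas <- atlas_builder(s$truth)
    tr <- if (is.null(transform_builder)) NULL else transform_builder(s)
    tab <- extract_label_metrics(sm$maps, atlas, tr)
    tab$subject <- s$id
    rows[[length(rows) + 1L]] <- tab
  }
  long <- do.call(rbind, c(rows, make.row.names = FALSE))
  merge_bilateral_labels(long)
}

# average _left/_right label pairs into side = "both" rows
merge_bilateral_labels <- function(long) {
  base <- sub("_(left|right)$", "", long$tract)
  side <- ifelse(grepl("_left$", long$tract), "left",
                 ifelse(grepl("_right$", long$tract), "right", "midline"))
  long$tract <- base
  long$side <- side
  out <- list()
  for (subj in unique(long$subject)) {
    sl <- long[long$subject == subj, ]
    for (tr in unique(sl$tract)) {
      st <- sl[sl$tract == tr, ]
      cols <- c("FA", "MD", "L1", "RD")
      gen <- st$generated & !is.na(st$FA)
      row <- st[1, ]
      row$side <- "both"
      if (any(gen)) {
        row[cols] <- colMeans(st[gen, cols, drop = FALSE])
        row$generated <- TRUE
      } else {
        row[cols] <- NA_real_
        row$generated <- FALSE
      }
      out[[length(out) + 1L]] <- row
    }
  }
  both <- do.call(rbind, c(out, make.row.names = FALSE))
  both$method <- "atlas"
  rbind(cbind(long, method = "atlas"), both[, c(names(long), "method")])
}

#' Evans' index of one subject, optionally after ACPC alignment
#'
#' @param subject a phantom subject (with truth masks and landmarks).
#' @param acpc realign the masks from the subject's landmarks first.
#' @return an `evans_index` object.
#' @export
subject_evans_index <- function(subject, acpc = TRUE) {
  truth <- subject$truth
  vent <- scalar_map(truth$ventricle_mask * 1, truth$affine, "mask")
  skull <- scalar_map(truth$skull_mask * 1, truth$affine, "mask")
  if (acpc) {
    tr <- acpc_align(truth$landmarks)
    vent <- resample_map(vent, tr, method = "nearest")
    skull <- resample_map(skull, tr, method = "nearest")
  }
  evans_index(vent, skull)
}
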