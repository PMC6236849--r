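# Treatment-schedule model and pipeline orchestration: an XML-backed
# treatment record, a strict four-stage per-fraction status machine
# (CBCT ready -> pseudo-CT ready -> Tx-dose ready -> cumulative dose ready),
# and run_course(), which drives phase matching, registration, pseudo-CT,
# dose reconstruction, accumulation and QA for every fraction.

fraction_statuses <- c("PENDING", "CBCT_READY", "PSEUDO_CT_READY",
                       "TXDOSE_READY", "CUMULATIVE_READY")
status_events <- c(cbct_arrived = "CBCT_READY",
                   pseudo_ct_done = "PSEUDO_CT_READY",
                   txdose_done = "TXDOSE_READY",
                   cumulative_done = "CUMULATIVE_READY")

#' Treatment record
#'
#' @param patient_id patient identifier.
#' @param fractions tibble with columns `index` (contiguous from 1), `date`
#'   (non-decreasing), `couch_dx`, `couch_dy`, `couch_dz` (mm) and `status`;
#'   missing couch/status columns are filled with 0 / `"PENDING"`. An
#'   optional `cbct_path` column records where the day images live.
#' @param plan_ids character vector naming the plan chain (first =
#'   pretreatment CT).
#' @return A `treatment_record`.
#' @export
treatment_record <- function(patient_id, fractions, plan_ids = "plan") {
  fractions <- tibble::as_tibble(fractions)
  if (!"status" %in% names(fractions)) fractions$status <- "PENDING"
  for (cc in c("couch_dx", "couch_dy", "couch_dz"))
    if (!cc %in% names(fractions)) fractions[[cc]] <- 0
  if (!identical(as.integer(fractions$index), seq_len(nrow(fractions))))
    stop("fraction indices must be contiguous from 1")
  if (nrow(fractions) > 1 && any(diff(as.Date(fractions$date)) < 0))
    stop("fraction dates must be non-decreasing")
  bad <- setdiff(unique(fractions$status), c(fraction_statuses, "FAILED"))
  if (length(bad))
    stop("illegal fraction status value: '", bad[1], "'")
  fractions$date <- as.Date(fractions$date)
  structure(list(patient_id = patient_id, plan_ids = plan_ids,
                 fractions = fractions),
            class = "treatment_record")
}

#' @export
print.treatment_record <- function(x, ...) {
  cat(sprintf("<treatment_record> patient %s, %d fractions\n",
              x$patient_id, nrow(x$fractions)))
  print(x$fractions, n = 10)
  invisible(x)
}

#' Advance a fraction's status
#'
#' Statuses advance strictly in the order PENDING -> CBCT_READY ->
#' PSEUDO_CT_READY -> TXDOSE_READY -> CUMULATIVE_READY; an event that does
#' not match the next legal transition is rejected, so no stage can be
#' skipped and no fraction ever moves backwards.
#'
#' @param record a [treatment_record()].
#' @param fraction_index 1-based fraction index.
#' @param event one of `"cbct_arrived"`, `"pseudo_ct_done"`,
#'   `"txdose_done"`, `"cumulative_done"` (or `"failed"`).
#' @return The updated record.
#' @export
advance_status <- function(record, fraction_index, event) {
  if (fraction_index < 1 || fraction_index > nrow(record$fractions))
    stop("no fraction ", fraction_index)
  cur <- record$fractions$status[fraction_index]
  if (event == "failed") {
    record$fractions$status[fraction_index] <- "FAILED"
    return(record)
  }
  if (!event %in% names(status_events))
    stop("unknown event '", event, "'")
  target <- status_events[[event]]
  cur_pos <- match(cur, fraction_statuses)
  tgt_pos <- match(target, fraction_statuses)
  if (is.na(cur_pos) || tgt_pos != cur_pos + 1L)
    stop("illegal transition for fraction ", fraction_index, ": '", cur,
         "' + ", event, " -> '", target, "' (statuses advance strictly in order)")
  record$fractions$status[fraction_index] <- target
  record
}

#' Write a treatment record as XML
#'
#' The document round-trips losslessly through [read_schedule_xml()].
#'
#' @param record a [treatment_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schedule_xml <- function(record, path) {
  doc <- xml2::xml_new_root("treatment_course",
                            patient_id = record$patient_id,
                            plan_ids = paste(record$plan_ids, collapse = ","))
  frs <- xml2::xml_add_child(doc, "fractions")
  for (i in seq_len(nrow(record$fractions))) {
    r <- record$fractions[i, ]
    fr <- xml2::xml_add_child(frs, "fraction",
                              index = as.character(r$index),
                              date = format(r$date),
                              status = r$status)
    xml2::xml_add_child(fr, "couch_correction",
                        dx = formatC(r$couch_dx, format = "g", digits = 17),
                        dy = formatC(r$couch_dy, format = "g", digits = 17),
                        dz = formatC(r$couch_dz, format = "g", digits = 17))
    if ("cbct_path" %in% names(r) && !is.na(r$cbct_path))
      xml2::xml_add_child(fr, "cbct_path", r$cbct_path)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a treatment record from XML
#'
#' Validates the schema as it reads: a `treatment_course` root with a
#' `fractions` element whose `fraction` children carry `index`, `date` and a
#' legal `status`; errors name the offending element and value.
#'
#' @param path XML file written by [write_schedule_xml()] (or hand-edited).
#' @return A [treatment_record()].
#' @export
read_schedule_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "treatment_course")
    stop("schema error at /: expected root <treatment_course>, found <",
         xml2::xml_name(doc), ">")
  pid <- xml2::xml_attr(doc, "patient_id")
  plan_ids <- strsplit(xml2::xml_attr(doc, "plan_ids"), ",")[[1]]
  frs <- xml2::xml_find_all(doc, "./fractions/fraction")
  rows <- lapply(seq_along(frs), function(i) {
    fr <- frs[[i]]
    status <- xml2::xml_attr(fr, "status")
    if (!status %in% c(fraction_statuses, "FAILED"))
      stop("schema error at /treatment_course/fractions/fraction[", i,
           "]/@status: illegal value '", status, "'")
    cc <- xml2::xml_find_first(fr, "./couch_correction")
    cb <- xml2::xml_find_first(fr, "./cbct_path")
    tibble::tibble(
      index = as.integer(xml2::xml_attr(fr, "index")),
      date = as.Date(xml2::xml_attr(fr, "date")),
      couch_dx = as.numeric(xml2::xml_attr(cc, "dx")),
      couch_dy = as.numeric(xml2::xml_attr(cc, "dy")),
      couch_dz = as.numeric(xml2::xml_attr(cc, "dz")),
      status = status,
      cbct_path = if (inherits(cb, "xml_missing")) NA_character_ else
        xml2::xml_text(cb))
  })
  fractions <- dplyr::bind_rows(rows)
  if (nrow(fractions) == 0) {
    fractions <- tibble::tibble(index = integer(), date = as.Date(character()),
                                couch_dx = numeric(), couch_dy = numeric(),
                                couch_dz = numeric(), status = character())
  } else if (all(is.na(fractions$cbct_path))) {
    fractions$cbct_path <- NULL
  }
  treatment_record(pid, fractions, plan_ids)
}

#' Run a full reconstruction course on phantom fixtures
#'
#' Drives the whole pipeline for every fraction of a simulated course:
#' phase matching of the planning 4D-CT to the day's 4D-CBCT, FOV-cropped
#' deformable registration of every matched phase pair, DVF expansion and
#' inversion, per-phase pseudo-CT, per-phase dose with the stand-in engine,
#' 4-D accumulation to the day's reference phase, warping to the planning CT
#' and cumulative summation, plus per-fraction contour QA. Stage failures
#' mark that fraction FAILED and the remaining fractions still run. Fully
#' deterministic given the course (which carries all seeds).
#'
#' @param course result of [make_course()].
#' @param beams list of [beam_spec()]s; default is a 3-beam arrangement
#'   aimed at the phantom tumor.
#' @param reg_params [registration_params()] used for every registration.
#' @param output_dir directory for reports and volumes; created if missing.
#' @param phases 1-based phase indices to reconstruct (all by default;
#'   phase weights renormalise over the subset).
#' @param prescription_gy per-fraction prescription: doses are normalised so
#'   the plan GTV D99 of one fraction equals this (`NULL` = raw engine
#'   units). The course-level reference is the prescription summed over all
#'   fractions.
#' @param write_volumes write reference pseudo-CT and dose volumes (.mha).
#' @return list with `record` (statuses advanced), `daily_doses` (on the
#'   plan CT), `cumulative` ([dose_grid()]), `plan_dose`, `report`
#'   (course-level DVH tibble), `qa` (per-fraction contour QA tibble),
#'   `pairings` (per-fraction phase-pairing tibbles) and `output_dir`.
#' @export
run_course <- function(course, beams = NULL,
                       reg_params = registration_params(pyramid_levels = 2L,
                                                        max_iter = 12L),
                       output_dir = tempfile("txdose-course-"),
                       phases = NULL, prescription_gy = 12,
                       write_volumes = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- course$plan
  spec <- plan$spec
  record <- course$record
  ref_idx <- plan$ct4d$reference_index
  geom <- geometry_of(plan$ct4d$phases[[1]])
  if (is.null(phases)) phases <- seq_len(spec$n_phases)
  w <- rep(1 / length(phases), length(phases))
  if (is.null(beams)) beams <- default_phantom_beams(spec)

  # plan dose: per-phase dose on the planning 4D-CT accumulated to the
  # reference phase with the exact plan fields
  plan_phase_doses <- lapply(phases, function(p)
    compute_dose(plan$ct4d$phases[[p]], beams))
  plan_dose <- accumulate_4d(plan_phase_doses,
                             plan$dvf_to_ref[phases], weights = w)
  # normalise so the per-fraction plan GTV D99 equals the prescription
  dose_scale <- 1
  if (!is.null(prescription_gy)) {
    d99 <- dvh_metrics(plan_dose, plan$rois$gtv)$value[1]
    if (d99 > 0) dose_scale <- prescription_gy / d99
    plan_dose$values <- plan_dose$values * dose_scale
  }
  # course-level reference: prescription summed over all fractions
  n_fx <- length(course$fractions)
  plan_total <- dose_grid(
    scalar_grid(plan_dose$values * n_fx, plan_dose$origin, plan_dose$spacing,
                unit_tag = "Gy"), provenance = "cumulative")

  fov <- course$fractions[[1]]$degrade$fov
  daily_doses <- vector("list", length(course$fractions))
  qa_rows <- list()
  pairings <- list()
  log_lines <- character()
  logf <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
  }

  for (f in seq_along(course$fractions)) {
    fr <- course$fractions[[f]]
    res <- tryCatch({
      record <- advance_status(record, f, "cbct_arrived")
      couch <- -fr$shift_mm   # recorded correction undoes the setup error
      pairing <- match_phases(plan$ct4d, fr$cbct4d, fov = fov)
      pairings[[f]] <- dplyr::mutate(pairing, fraction = f)
      logf("fraction %d: phases matched (max |delta| %.2f mm)",
           f, max(pairing$delta_mm))

      phase_doses <- vector("list", length(phases))
      day_to_phase <- vector("list", length(phases))
      forward_ref <- NULL
      pseudo_ref <- NULL
      for (pi in seq_along(phases)) {
        p <- phases[pi]
        ct_phase <- plan$ct4d$phases[[pairing$ct_phase[p]]]
        cbct_phase <- fr$cbct4d$phases[[p]]
        cropped <- crop_to_fov(ct_phase, fov)
        fwd_c <- register(cropped$grid, cbct_phase, reg_params)
        fwd <- expand_dvf(fwd_c, geom, cropped$record,
                          sigma_mm = reg_params$sigma_diffusion_mm * 2)
        pair <- dvf_pair(fwd, geom)
        pseudo <- generate_pseudo_ct(ct_phase, pair$backward, geom,
                                     fov = fov, patch_phase_ct = ct_phase,
                                     couch_shift_mm = -couch)
        phase_doses[[pi]] <- compute_dose(pseudo, beams,
                                          output_scale = dose_scale)
        if (p == ref_idx) { forward_ref <- fwd; pseudo_ref <- pseudo }
        # day reference -> day phase field: compose the exact plan-CT phase
        # fields is not available clinically; register day phases directly
        day_to_phase[[pi]] <- if (p == ref_idx) NULL else
          register(fr$cbct4d$phases[[ref_idx]], cbct_phase, reg_params)
      }
      record <- advance_status(record, f, "pseudo_ct_done")

      day_dose <- accumulate_4d(phase_doses, day_to_phase, weights = w)
      # pull the day dose onto the planning CT through the reference-phase
      # forward field (CT -> CBCT)
      daily_doses[[f]] <- warp_dose(day_dose, forward_ref)
      record <- advance_status(record, f, "txdose_done")

      # propagated GTV on the day grid vs the planned GTV
      prop <- warp_image(plan$rois$gtv$grid,
                         invert_dvf(forward_ref, geom), fill = 0)
      prop$values[] <- as.double(prop$values > 0.5)
      prop_roi <- roi_mask(prop, "GTV_propagated", "target",
                           allow_empty = TRUE)
      qa <- contour_metrics(plan$rois$gtv, prop_roi)
      qa$fraction <- f
      qa_rows[[f]] <- qa
      if (write_volumes) {
        write_volume(pseudo_ref,
                     file.path(output_dir, sprintf("fx%02d_pseudo_ct.mha", f)))
        write_volume(daily_doses[[f]],
                     file.path(output_dir, sprintf("fx%02d_dose.mha", f)))
      }
      TRUE
    }, error = function(e) {
      logf("fraction %d FAILED: %s", f, conditionMessage(e))
      record <<- advance_status(record, f, "failed")
      FALSE
    })
    if (!res) daily_doses[f] <- list(NULL)
  }

  ok <- !vapply(daily_doses, is.null, TRUE)
  cumulative <- NULL
  if (any(ok)) {
    cumulative <- accumulate_course(daily_doses[ok],
                                    dates = record$fractions$date[ok])
    for (f in which(ok)) record <- advance_status(record, f, "cumulative_done")
  }
  report <- course_report(plan_total, daily_doses[ok], cumulative,
                          rois = plan$rois[c("gtv", "lung", "cord")],
                          prescription_gy = prescription_gy)
  qa <- if (length(qa_rows)) dplyr::bind_rows(qa_rows) else tibble::tibble()

  utils::write.csv(report, file.path(output_dir, "course_report.csv"),
                   row.names = FALSE)
  if (nrow(qa))
    utils::write.csv(qa, file.path(output_dir, "contour_qa.csv"),
                     row.names = FALSE)
  if (length(pairings))
    utils::write.csv(dplyr::bind_rows(pairings),
                     file.path(output_dir, "phase_pairing.csv"),
                     row.names = FALSE)
  write_schedule_xml(record, file.path(output_dir, "schedule.xml"))
  writeLines(log_lines, file.path(output_dir, "run.log"))

  list(record = record, daily_doses = daily_doses, cumulative = cumulative,
       plan_dose = plan_dose, plan_total = plan_total, report = report,
       qa = qa, pairings = pairings, output_dir = output_dir)
}

#' Default three-beam arrangement aimed at the phantom tumor
#'
#' @param spec a [phantom_spec()].
#' @param field_margin_mm aperture margin beyond the tumor diameter.
#' @return list of [beam_spec()]s.
#' @export
default_phantom_beams <- function(spec, field_margin_mm = 10) {
  iso <- spec$tumor_center + c(0, 0, tumor_amp(spec) / 2)
  fs <- 2 * spec$tumor_radius + tumor_amp(spec) + field_margin_mm
  dirs <- list(c(0, 1, 0), c(1, 0, 0), c(-1, 0.3, 0))
  lapply(dirs, function(d) beam_spec(isocenter = iso, direction = d,
                                     field_size = c(fs, fs)))
}
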