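# Packaged fixtures

## table1_patients.csv

Per-subject records for the brain-tumor DTI-ALPS cohort: 30 consecutive
patients, 24 included (excluded rows keep demographics and tumor ADC but have
empty ALPS cells and `included = FALSE`). Columns:

- `id` — patient number (integer, unique)
- `age` — years at scan
- `sex` — `male` | `female`
- `alps_ipsi`, `alps_contra` — DTI-ALPS index of the tumor-ipsilateral and
  contralateral hemisphere (dimensionless; empty for excluded subjects)
- `tumor_adc` — mean ADC of a 5.3 mm² ROI at the tumor center, in
  1e-6 mm²/s (values ~75–2930)
- `event` — `first_diagnosis` | `local_recurrence` | `distance_recurrence`
- `tumor_type` — `primary` | `metastasis` (the subject with an unclear
  histology is counted as primary, consistent with the cohort totals
  17 primary + 7 metastases)
- `details`, `tumor_location` — free-text histology and site
- `tumor_side` — `left` | `right` | `intraventricular`
- `ptbe` — peritumoral brain edema present (`yes`/`no`)
- `roi_in_ptbe` — TRUE where the ipsilateral ALPS ROIs had to be placed
  inside the edema (5 included subjects)
- `included` — passes the inclusion criteria (adult, artifact-free DTI,
  periventricular vein area unaffected)

Known transcription notes:

- The tabulated per-row tumor ADC values average to 1618.94 over the 24
  included subjects; a summary figure of 1618.42 quoted for this cohort does
  not recompute exactly from the rows. The rows are kept as tabulated, not
  reconciled.
- The included-patient age sd recomputes to 12.99 (quoted elsewhere as
  12.71); the mean 56.58 recomputes exactly.

## table2_controls.csv

Twelve healthy controls used for sex- and age-matching (±2 years). Columns
`id, sex, age, alps_right, alps_left, matched_patients`
(`matched_patients` is a `;`-separated list of patient ids; controls may
serve several patients). Transcription note: control 2's row runs the left
index and matched-patient digits together; it is transcribed as left = 1.30,
matched patient 1 — the only reading that matches the remaining unmatched
included patient (1: male, 24 y vs control 2: male, 24 y) and reproduces the
printed column means (right 1.29, left 1.26) and left median (1.31).

## scheme64.bval / scheme64.bvec

FSL-dialect gradient table: one b = 0 measurement plus 64 directions at
b = 1000 s/mm², laid out by a deterministic electrostatic-repulsion
optimization on the hemisphere (antipodally symmetric energy). Used as the
default acquisition scheme of the synthetic phantom.

## rois_phantom.json

Example ROI sidecar for the default phantom: 2x2x1 projection and
association ROIs (0-based `start_voxel`, half-open extents) on the central
slice.
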