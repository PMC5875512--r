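# Bundled reference data

`xvi_point_doses.csv`, `xvi_dli.csv` and `xvi_factory_protocols.json` are
published reference measurements for an Elekta Synergy XVI kV CBCT system:

- Point doses (cGy per 100 mAs) measured with an NE2571 thimble chamber
  per TG-61 in CIRS head (100 kVp; full and 200-degree half rotation) and
  body (120 kVp; full rotation) phantoms, at the centre and at four
  peripheral positions (A, L, P, R; 2 cm deep for head, 5 cm for body).
- Dose line integrals (mGy.cm per 100 mAs) from diode-array longitudinal
  profiles renormalised to the absolute point doses. One DLI pair is
  published per collimator; the half-rotation head entries reuse the same
  profile integrals with the half-rotation point doses. `dlp_published` is
  the DLP_CBCT value as printed in the source tables; note the published
  chest-protocol DLP appears both as 665.1 and 665.2 mGy.cm in different
  places in the source — 665.1 is carried here.
- Factory protocol presets (tube settings, collimator, arc) for the three
  XVI volume-view protocols.

These values characterise one particular machine and are intended as a
worked reference and test fixture. Replace them with your own measurements
(same file schemas) for clinical use; the package never silently mixes the
bundled values with user data.
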