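# Demonstration pipeline: a 160 mm soft-tissue cylinder on a downscaled
# 128 x 128 detector (2.4 mm pitch), 90 views, 5 x 40 mm thickness
# groups.  Runs end to end in well under a minute on one CPU.
seed: 1
i0: 10000.0
noise: false
geometry:
  dso: 500.0
  dsd: 786.0
  pitch: 2.4
  det_rows: 128
  det_cols: 128
  n_views: 90
phantom:
  diameter_mm: 160.0
  voxel_mm: 2.5
  inserts: none
mlem:
  max_iter: 5
  tol: 1.0e-4
recon:
  filter: shepp-logan
  cutoff: 0.6
  npix: 128
  voxel_mm: 1.5
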