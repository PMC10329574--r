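# Default six-center synthetic study: per-center frame counts and polyp
# prevalences at 1920x1080. Same configuration as default_six_center_spec().
seed: 1
centers:
  - center_id: center1
    n_images: 256
    prevalence: 0.98
  - center_id: center2
    n_images: 276
    prevalence: 0.89
  - center_id: center3
    n_images: 457
    prevalence: 0.99
  - center_id: center4
    n_images: 227
    prevalence: 0.64
  - center_id: center5
    n_images: 208
    prevalence: 0.99
  - center_id: center6
    n_images: 88
    prevalence: 0.94
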