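# Demo pipeline configuration: simulated three-set variant catalogs with
# class-specific predicted ddG, two class-wise comparisons, and five
# noiseless two-state denaturation curves generated from the measured
# AR-LBD panel parameters (see ar_lbd_reference.tsv).
seed: 20260101
test: welch
temperature_K: 298.15
alpha_window: [0.02, 0.98]
ddg_threshold: 3.0

catalog:
  simulate:
    n_disease: 337
    n_somatic: 323
    n_polymorphism: 39

comparisons:
  - {a: HGMD, b: polymorphism}
  - {a: COSMIC, b: polymorphism}

denaturation:
  reference: WT
  curves:
    - {id: WT,    dg0: -5.3, m_value: 1.7}
    - {id: I738T, dg0: -3.0, m_value: 1.3}
    - {id: C807Y, dg0: -2.2, m_value: 1.1}
    - {id: W752R, dg0: -1.7, m_value: 0.9}
    - {id: L813F, dg0: -1.5, m_value: 0.6}
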