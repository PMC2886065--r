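sample_id	batch_label
batch1_s01	batch1
batch1_s02	batch1
batch1_s03	batch1
batch1_s04	batch1
batch1_s05	batch1
batch1_s06	batch1
batch1_s07	batch1
batch1_s08	batch1
batch1_s09	batch1
batch1_s10	batch1
batch2_s01	batch2
batch2_s02	batch2
batch2_s03	batch2
batch2_s04	batch2
batch2_s05	batch2
batch2_s06	batch2
batch2_s07	batch2
batch2_s08	batch2
batch2_s09	batch2
batch2_s10	batch2
batch2_s11	batch2
batch2_s12	batch2
batch2_s13	batch2
batch2_s14	batch2
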