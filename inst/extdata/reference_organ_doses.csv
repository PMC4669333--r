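# Reference organ absorbed doses (mGy/MBq), mean and SD over two animals,
# for an F-18 NIS tracer (tetrafluoroborate), 70-kg adult model.
# sphere_model = 1 marks salivary glands dosed with the unit-density
# sphere model rather than phantom S values.
organ,dose_mgy_per_mbq,sd,sphere_model
adrenals,1.44E-02,7.1E-05,0
brain,4.54E-03,5.3E-04,0
breasts,9.52E-03,2.8E-04,0
gallbladder_wall,1.46E-02,7.1E-05,0
lli_wall,1.42E-02,1.4E-04,0
small_intestine,1.43E-02,0.0E+00,0
stomach_wall,7.86E-02,1.9E-02,0
uli_wall,1.42E-02,0.0E+00,0
heart_wall,1.77E-02,7.1E-04,0
kidneys,2.25E-02,3.5E-04,0
liver,1.27E-02,2.8E-04,0
lungs,1.78E-02,2.1E-03,0
muscle,1.14E-02,2.1E-04,0
ovaries,1.44E-02,0.0E+00,0
pancreas,1.85E-02,1.1E-03,0
red_marrow,1.66E-02,1.4E-04,0
osteogenic_cells,2.01E-02,4.9E-04,0
skin,8.68E-03,2.1E-04,0
spleen,1.42E-02,7.8E-04,0
testes,1.12E-02,7.1E-05,0
thymus,1.18E-02,3.5E-04,0
thyroid,4.23E-02,2.1E-04,0
urinary_bladder_wall,4.79E-02,1.5E-02,0
uterus,1.56E-02,5.7E-04,0
parotid_gland,4.13E-02,2.1E-02,1
submandibular_gland,2.74E-02,1.7E-02,1
total_body,1.18E-02,1.4E-04,0
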