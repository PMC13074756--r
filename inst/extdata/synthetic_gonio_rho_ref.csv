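bin_center_nm,side,rho_ref,tau
445,adaxial,0.055005247419334095,0.042019496447621936
555,adaxial,0.15918571053573213,0.17616121287673947
655,adaxial,0.05572003416993024,0.0427962296584215
735,adaxial,0.42617834255260195,0.42487213562407283
445,abaxial,0.06160587710965419,0.042019496447621936
555,abaxial,0.17828799580002,0.17616121287673947
655,abaxial,0.062406438270321885,0.0427962296584215
735,abaxial,0.4773197436589142,0.42487213562407283
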