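# karyomorph packaged fixture: karyotype features of 16 karyotyped accessions
# (15 Daucus accessions + the outgroup Orlaya daucoides); lengths in micrometres,
# CV_CL / CV_CI / M_CA dimensionless x100, stebbins = symmetry class token.
accession,taxon,accession_no,ploidy,2n,kf,thcl,clr_min,clr_max,cv_cl,cv_ci,m_ca,stebbins
aur,Daucus aureus,PI 319403,2,22,1m + 10sm,23.50,1.54,2.89,17.85,10.23,36.89,3A
cap1,Daucus carota subsp. capillifolius,PI 279764,2,18,8sm + 1st,28.67,2.32,4.08,17.68,22.12,34.63,3A
cap2,Daucus carota subsp. capillifolius,Ames 30198,2,18,8sm + 1st,22.19,1.89,3.36,18.33,16.94,34.79,3A
car1,Daucus carota subsp. carota,PI 274297,2,18,7sm + 2st,28.95,2.38,4.03,17.26,20.19,34.01,3A
car2,Daucus carota subsp. carota,PI 478369,2,18,1m + 6sm + 2st,24.56,2.07,3.61,16.21,18.24,33.36,2A
car3,Daucus carota subsp. carota,PI 478861,2,18,1m + 4sm + 4st,31.15,2.62,4.33,15.13,26.50,35.89,3A
car4,Daucus carota subsp. carota,PI 652393,2,18,6sm + 3st,25.23,2.04,3.45,15.52,19.38,35.79,3A
gum1,Daucus carota subsp. gummifer,PI 478883,2,18,5sm + 4st,33.47,2.72,4.77,17.42,24.31,35.94,3A
gum2,Daucus carota subsp. gummifer,Ames 26383,2,18,1m + 5sm + 3st,28.32,2.39,4.20,17.41,18.45,34.06,2A
sat1,Daucus carota subsp. sativus,'Amsterdam',2,18,7sm + 2st,29.86,2.55,4.16,16.04,24.37,35.73,3A
sat2,Daucus carota subsp. sativus,'Dolanka',2,18,1m + 8sm,29.90,2.65,4.26,14.70,18.93,31.04,3A
sat3,Daucus carota subsp. sativus,DH1,2,18,8sm + 1st,28.08,2.42,3.91,14.38,19.65,34.45,3A
rou,Daucus rouyi,PI 674284,2,20,2m + 8sm,35.50,2.45,5.12,20.41,14.47,38.74,3A
sah,Daucus sahariensis,Ames 29097,2,18,2m + 7sm,27.97,2.24,4.20,20.46,13.68,32.28,3A
syr,Daucus syrticus,Ames 29108,2,18,6m + 3sm,26.86,2.25,4.07,17.66,9.39,26.08,2A
orl,Orlaya daucoides,PI 649477,2,16,2m + 6sm,35.61,3.27,7.73,30.47,12.16,20.55,2A
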