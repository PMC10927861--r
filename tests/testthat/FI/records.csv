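"study_id","country","strain","leaf_type","microbes","dose_g_per_kg","phase_start_day","phase_end_day","outcome","mean_c","sd_c","se_c","n_c","mean_t","sd_t","se_t","n_t"
"fix-01","China","Arbor Acres","G. biloba","A. niger",2,1,21,"FI",95,4,,8,99,5,,8
"fix-02","China","Arbor Acres","G. biloba","A. niger",5,1,21,"FI",96,5,,8,97,4,,8
"fix-03","China","Arbor Acres","G. biloba","A. niger + C. utilis",3.5,22,42,"FI",160,8,,10,165,9,,10
"fix-04","China","Arbor Acres","G. biloba","A. niger + C. utilis",8,22,42,"FI",158,9,,10,150,10,,10
"fix-05","China","Arbor Acres","G. biloba","C. utilis",10,1,42,"ADG",52,3,,6,55,3.2,,6
"fix-06","China","Arbor Acres","G. biloba","B. subtilis",12,1,56,"ADG",55,3.6,1.2,9,58,3.3,1.1,9
"fix-07","China","Yellow feathered","M. alba","B. subtilis + Lactobacillus + Saccharomycetes",2.5,0,21,"FCR",1.8,0.1,,8,1.72,0.11,,8
"fix-08","China","Yellow feathered","M. alba","B. subtilis + Lactobacillus + Saccharomycetes",6,22,56,"FCR",1.75,0.12,,8,1.7,0.1,,8
"fix-09","Indonesia","Yellow feathered","M. alba","B. subtilis + Lactobacillus + Saccharomycetes",14,1,42,"FI",98,6,,12,96,7,,12
"fix-10","Indonesia","Lohmann","S. androgynus","T. harzianum",4,15,35,"FI",90,3.67423461417477,1.5,6,88,3.42928563989645,1.4,6
"fix-11","Indonesia","Lohmann","S. androgynus","T. harzianum",11,1,56,"ADG",50,4,,10,48,5,,10
"fix-12","Indonesia","Lohmann","C. album","B. subtilis + L. plantarum + S. cerevisiae",5.5,1,42,"FCR",1.7,0.09,,8,1.68,0.08,,8
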