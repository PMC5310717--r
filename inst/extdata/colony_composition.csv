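date,type,F,M,NAsex,total
2012-05-22,myotis,38,1,1,40
2012-05-22,blythii,0,0,0,0
2012-05-22,hybrid,1,0,0,1
2012-06-20,myotis,24,1,4,29
2012-06-20,blythii,1,0,0,1
2012-06-20,hybrid,1,0,0,1
2012-07-10,myotis,35,2,4,41
2012-07-10,blythii,0,0,0,0
2012-07-10,hybrid,1,0,1,2
2012-08-03,myotis,32,1,3,36
2012-08-03,blythii,1,0,1,2
2012-08-03,hybrid,3,0,0,3
2012-08-29,myotis,6,5,0,11
2012-08-29,blythii,6,2,2,10
2012-08-29,hybrid,7,0,0,7
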