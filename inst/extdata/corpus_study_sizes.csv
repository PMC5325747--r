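first_author,treatment,n_cases
Brisman,SRS,49
Nicol,SRS,42
Chang,SRS,15
Shaya,SRS,40
Lim,SRS,41
Tawk,SRS,38
Pollock,Both,83
Massager,SRS,109
Fountas,SRS,77
Balamucki,SRS,172
Fountas,SRS,57
Longhi,SRS,92
Brisman,SRS,61
Lorenzoni,SRS,89
Matsuda,SRS,100
Huang,SRS,89
Linskey,Both,70
Oh,Both,45
Dhople,SRS,112
Knafo,SRS,67
Han,SRS,51
Fariselli,SRS,33
Adler,SRS,46
Park,SRS,39
Chen,SRS,40
Sheehan,SRS,63
Hayashi,SRS,130
Park,SRS,17
Park,SRS,62
Tuleasca,SRS,497
Fraioli,SRS,23
Attia,SRS,19
Lee,SRS,91
Flickinger,SRS,174
Lazzara,SRS,16
Young,SRS,250
Lee,SRS,21
Lucas,SRS,446
Song,SRS,20
Xu,SRS,99
Tyler-Kabara,MVD,1739
Ashkan,MVD,80
Olson,MVD,156
Zakrzewska,MVD,220
Aryan,MVD,19
Sindou,MVD,362
Laghmari,MVD,51
Tarricone,MVD,20
Bond,MVD,119
Oesman,MVD,120
Chakravarthi,MVD,40
Chen,MVD,67
Zhong,MVD,1274
Sandel,MVD,243
Reddy,MVD,60
Shibahashi,MVD,65
Sarnvivad,MVD,98
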