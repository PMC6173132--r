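scan_id,volunteer_id,sonographer_id,expert_id,qualification,y_left,y_right
S0001,S0001,A,7,sonographer,0,1
S0001,S0001,A,8,sonographer,1,1
S0002,S0002,A,1,gynaecologist,1,1
S0002,S0002,A,2,gynaecologist,0,1
S0002,S0002,A,3,gynaecologist,1,1
S0003,S0003,A,1,gynaecologist,1,1
S0003,S0003,A,2,gynaecologist,1,1
S0003,S0003,A,3,gynaecologist,1,1
S0004,S0004,A,4,radiologist,0,0
S0004,S0004,A,5,radiologist,0,0
S0004,S0004,A,6,sonographer,1,1
S0005,S0005,A,4,radiologist,1,0
S0005,S0005,A,5,radiologist,0,0
S0005,S0005,A,6,sonographer,1,1
S0006,S0006,A,7,sonographer,0,1
S0006,S0006,A,8,sonographer,1,1
S0007,S0007,B,7,sonographer,0,1
S0007,S0007,B,8,sonographer,1,1
S0008,S0008,B,1,gynaecologist,1,1
S0008,S0008,B,2,gynaecologist,1,1
S0008,S0008,B,3,gynaecologist,1,1
S0009,S0009,B,4,radiologist,1,1
S0009,S0009,B,5,radiologist,1,1
S0009,S0009,B,6,sonographer,0,1
S0010,S0010,B,4,radiologist,1,1
S0010,S0010,B,5,radiologist,1,0
S0010,S0010,B,6,sonographer,1,1
S0011,S0011,B,1,gynaecologist,1,0
S0011,S0011,B,2,gynaecologist,1,1
S0011,S0011,B,3,gynaecologist,0,0
S0012,S0012,B,7,sonographer,0,1
S0012,S0012,B,8,sonographer,0,1
S0013,S0013,C,7,sonographer,1,1
S0013,S0013,C,8,sonographer,1,1
S0014,S0014,C,7,sonographer,1,1
S0014,S0014,C,8,sonographer,1,1
S0015,S0015,C,4,radiologist,1,1
S0015,S0015,C,5,radiologist,1,1
S0015,S0015,C,6,sonographer,1,0
S0016,S0016,C,1,gynaecologist,1,1
S0016,S0016,C,2,gynaecologist,1,1
S0016,S0016,C,3,gynaecologist,1,
S0017,S0017,C,4,radiologist,1,1
S0017,S0017,C,5,radiologist,1,1
S0017,S0017,C,6,sonographer,1,1
S0018,S0018,C,1,gynaecologist,1,1
S0018,S0018,C,2,gynaecologist,1,1
S0018,S0018,C,3,gynaecologist,1,1
S0019,S0019,D,4,radiologist,1,1
S0019,S0019,D,5,radiologist,0,0
S0019,S0019,D,6,sonographer,1,1
S0020,S0020,D,7,sonographer,0,0
S0020,S0020,D,8,sonographer,1,0
S0021,S0021,D,1,gynaecologist,1,1
S0021,S0021,D,2,gynaecologist,1,1
S0021,S0021,D,3,gynaecologist,1,1
S0022,S0022,D,7,sonographer,0,0
S0022,S0022,D,8,sonographer,1,1
S0023,S0023,D,1,gynaecologist,1,1
S0023,S0023,D,2,gynaecologist,1,0
S0023,S0023,D,3,gynaecologist,0,0
S0024,S0024,D,4,radiologist,1,1
S0024,S0024,D,5,radiologist,1,1
S0024,S0024,D,6,sonographer,1,1
S0025,S0025,E,1,gynaecologist,1,1
S0025,S0025,E,2,gynaecologist,1,1
S0025,S0025,E,3,gynaecologist,1,1
S0026,S0026,E,1,gynaecologist,1,1
S0026,S0026,E,2,gynaecologist,1,1
S0026,S0026,E,3,gynaecologist,1,1
S0027,S0027,E,4,radiologist,1,1
S0027,S0027,E,5,radiologist,1,
S0027,S0027,E,6,sonographer,1,1
S0028,S0028,E,7,sonographer,1,1
S0028,S0028,E,8,sonographer,1,1
S0029,S0029,E,4,radiologist,1,1
S0029,S0029,E,5,radiologist,1,1
S0029,S0029,E,6,sonographer,1,1
S0030,S0030,E,7,sonographer,0,1
S0030,S0030,E,8,sonographer,1,1
S0031,S0031,F,7,sonographer,0,0
S0031,S0031,F,8,sonographer,1,1
S0032,S0032,F,1,gynaecologist,1,1
S0032,S0032,F,2,gynaecologist,1,1
S0032,S0032,F,3,gynaecologist,1,1
S0033,S0033,F,1,gynaecologist,1,1
S0033,S0033,F,2,gynaecologist,1,
S0033,S0033,F,3,gynaecologist,1,1
S0034,S0034,F,4,radiologist,1,1
S0034,S0034,F,5,radiologist,1,1
S0034,S0034,F,6,sonographer,1,1
S0035,S0035,F,4,radiologist,1,1
S0035,S0035,F,5,radiologist,1,1
S0035,S0035,F,6,sonographer,1,1
S0036,S0036,F,7,sonographer,1,1
S0036,S0036,F,8,sonographer,1,1
S0037,S0037,G,4,radiologist,1,1
S0037,S0037,G,5,radiologist,1,0
S0037,S0037,G,6,sonographer,0,1
S0038,S0038,G,1,gynaecologist,1,1
S0038,S0038,G,2,gynaecologist,1,1
S0038,S0038,G,3,gynaecologist,1,0
S0039,S0039,G,4,radiologist,1,1
S0039,S0039,G,5,radiologist,0,0
S0039,S0039,G,6,sonographer,1,1
S0040,S0040,G,1,gynaecologist,1,1
S0040,S0040,G,2,gynaecologist,1,1
S0040,S0040,G,3,gynaecologist,1,1
S0041,S0041,G,7,sonographer,1,0
S0041,S0041,G,8,sonographer,1,0
S0042,S0042,G,7,sonographer,0,1
S0042,S0042,G,8,sonographer,1,1
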