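#!/usr/bin/env python
"""Minimal static file server with HTTP Range support, for offline tests.

Usage: python range_server.py DOCROOT READYFILE
Binds 127.0.0.1 on an ephemeral port and writes "PID PORT" to READYFILE
once listening.  Set NO_RANGES=1 in the environment to serve full bodies
only (simulates a server without range support).
"""
import http.server
import os
import re
import socketserver
import sys


class RangeHandler(http.server.SimpleHTTPRequestHandler):
    def _load(self):
        path = self.translate_path(self.path)
        if not os.path.isfile(path):
            self.send_error(404)
            return None
        with open(path, "rb") as fh:
            return fh.read()

    def do_HEAD(self):
        data = self._load()
        if data is None:
            return
        self.send_response(200)
        self.send_header("Accept-Ranges", "none" if NO_RANGES else "bytes")
        self.send_header("Content-Length", str(len(data)))
        self.end_headers()

    def do_GET(self):
        data = self._load()
        if data is None:
            return
        rng = self.headers.get("Range")
        m = re.match(r"bytes=(\d+)-(\d*)$", rng or "")
        if m and not NO_RANGES:
            start = int(m.group(1))
            end = int(m.group(2)) if m.group(2) else len(data) - 1
            if start >= len(data):
                self.send_response(416)
                self.send_header("Content-Range", "bytes */%d" % len(data))
                self.end_headers()
                return
            end = min(end, len(data) - 1)
            body = data[start:end + 1]
            self.send_response(206)
            self.send_header("Content-Range",
                             "bytes %d-%d/%d" % (start, end, len(data)))
        else:
            body = data
            self.send_response(200)
        self.send_header("Content-Length", str(len(body)))
        self.end_headers()
        self.wfile.write(body)

    def log_message(self, *args):
        pass


if __name__ == "__main__":
    docroot, readyfile = sys.argv[1], sys.argv[2]
    NO_RANGES = os.environ.get("NO_RANGES", "") == "1"
    os.chdir(docroot)
    socketserver.TCPServer.allow_reuse_address = True
    with socketserver.TCPServer(("127.0.0.1", 0), RangeHandler) as srv:
        port = srv.server_address[1]
        with open(readyfile, "w") as fh:
            fh.write("%d %d" % (os.getpid(), port))
        srv.serve_forever()
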